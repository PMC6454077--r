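# Shared fixtures. The default factorial run is expensive (~30 s), so it is
# computed once per test session and reused by every test that analyses it.
.fixtures <- new.env(parent = emptyenv())

defaultRows <- function() {
  if (is.null(.fixtures$rows))
    .fixtures$rows <- runExperiment(defaultConfig(), seed = 101)
  .fixtures$rows
}

denseAif <- function() {
  if (is.null(.fixtures$aif))
    .fixtures$aif <- generateAif(aifParameters())
  .fixtures$aif
}

# Closed-form tissue responses used as independent oracles ------------------

# boxcar arterial enhancement A on [t1, t2]:
#   C(t) = A k/lambda (1 - exp(-lambda (t - t1)))          t in [t1, t2]
#   C(t) = C(t2) exp(-lambda (t - t2))                     t > t2
boxcarTissueOracle <- function(t, A, t1, t2, kin, lambda) {
  ct <- numeric(length(t))
  on <- t >= t1 & t <= t2
  ct[on] <- A * kin / lambda * (1 - exp(-lambda * (t[on] - t1)))
  cEnd <- A * kin / lambda * (1 - exp(-lambda * (t2 - t1)))
  after <- t > t2
  ct[after] <- cEnd * exp(-lambda * (t[after] - t2))
  ct
}

# exponential arterial enhancement A exp(-mu (t - t0)) from t0:
#   C(t) = A k (exp(-mu s) - exp(-lambda s)) / (lambda - mu),  s = t - t0
expTissueOracle <- function(t, A, t0, mu, kin, lambda) {
  s <- pmax(t - t0, 0)
  A * kin * (exp(-mu * s) - exp(-lambda * s)) / (lambda - mu)
}

kinOf <- function(kin) kin@extractionE * kin@flowF * kin@tissueDensity / 60
lambdaOf <- function(kin) kinOf(kin) / (kin@distVolume * kin@tissueDensity)
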