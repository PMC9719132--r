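# Small-scene configurations used by the unit tests to keep runtimes down;
# acceptance checks use the full-size defaults.

smallSceneConfig <- function(...) {
  generatorConfig(imageSize = c(120L, 120L), ...)
}

smallPipelineConfig <- function(...) {
  pipelineConfig(resize = c(64L, 64L), ...)
}

# Synthetic Gaussian feature table for classifier tests: `informative` columns
# get a mean shift of `delta` for the positive class.
makeToyTable <- function(n, p = 10, nPos = round(n * 0.25), delta = 2.5,
                         informative = 3, seed = 1) {
  set.seed(seed)
  label <- sample(c(rep(1L, nPos), rep(0L, n - nPos)))
  x <- matrix(rnorm(n * p), n, p)
  for (j in seq_len(informative)) x[label == 1L, j] <- x[label == 1L, j] + delta
  colnames(x) <- paste0("f", seq_len(p))
  data.frame(id = sprintf("s%03d", seq_len(n)), label = label, x,
             stringsAsFactors = FALSE, check.names = FALSE)
}
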