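# Shared, lazily built fixtures.  Everything is generated in code from the
# phantom generator; expensive objects (trained forest, rendered fields)
# are cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixtureSpectra <- function() {
  if (is.null(.fixtures$spectra))
    .fixtures$spectra <- makeStainSpectra(defaultBandCenters())
  .fixtures$spectra
}

# one preprocessed phantom field with scene + truth, cached by key
fixtureField <- function(grade, seed, shape = c(400L, 400L)) {
  key <- sprintf("field_%s_%d_%d", grade, seed, shape[1L])
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulateFields(grade, 1L, fieldShape = shape,
                                       seed = seed)[[1L]]
  .fixtures[[key]]
}

# nucleus forest trained on one dedicated field per grade (seeds disjoint
# from every evaluation field used in the tests)
fixtureModel <- function() {
  if (is.null(.fixtures$model)) {
    tr <- lapply(c("normal", "poorly", "well"),
                 function(g) fixtureField(g, seed = 990L))
    .fixtures$model <- trainNucleusRF(lapply(tr, `[[`, "stack"),
                                      lapply(tr, `[[`, "truth"),
                                      seed = 5L)
  }
  .fixtures$model
}

maskIoUForTest <- function(a, b) sum(a & b) / sum(a | b)

# brute-force O(n^2) ordered-pair AUC oracle (ties count 1/2)
pairCountAUC <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# centroid-hit recall of true nuclei against a segmentation mask
nucleusRecall <- function(scene, mask) {
  sc <- scene@nuclei
  if (nrow(sc) == 0L) return(NA_real_)
  hits <- mapply(function(r, c) mask[round(r), round(c)], sc$row, sc$col)
  mean(hits)
}

# uniform gray stack with the three working bands, for degenerate inputs
flatStack <- function(value = 200, dim = c(220L, 220L)) {
  SpectralStack(list(matrix(value, dim[1L], dim[2L]),
                     matrix(value, dim[1L], dim[2L]),
                     matrix(value, dim[1L], dim[2L])),
                wavelengths = c(520, 600, 630))
}
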