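#' @import methods
NULL

#' ParetoArchive: bounded store of mutually nondominated solutions
#'
#' Positions and objective vectors of the nondominated solutions retained
#' during a multi-objective search. The archive is valid only if no entry
#' dominates another and its size does not exceed `capacity`.
#'
#' @slot positions Numeric matrix, one row per entry (decision vectors).
#' @slot objectives Numeric matrix, one row per entry (all-minimized).
#' @slot capacity Maximum number of entries.
#' @export
setClass("ParetoArchive",
         representation(positions = "matrix", objectives = "matrix",
                        capacity = "numeric"),
         prototype(positions = matrix(0, 0, 0),
                   objectives = matrix(0, 0, 0), capacity = 50))

setValidity("ParetoArchive", function(object) {
  n <- nrow(object@objectives)
  if (nrow(object@positions) != n)
    return("positions and objectives must have the same number of rows")
  if (n > object@capacity)
    return("archive exceeds capacity")
  if (n > 1L) {
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i != j && dominates(object@objectives[i, ], object@objectives[j, ]))
        return("archive entries must be mutually nondominated")
  }
  TRUE
})

#' Construct an empty Pareto archive
#'
#' @param capacity Maximum number of retained solutions.
#' @param d Decision-space dimension.
#' @param m Objective-space dimension (default 2).
#' @return A [ParetoArchive-class] object.
#' @export
paretoArchive <- function(capacity = 50L, d = 1L, m = 2L) {
  new("ParetoArchive",
      positions = matrix(numeric(0), 0L, d),
      objectives = matrix(numeric(0), 0L, m),
      capacity = as.numeric(capacity))
}

#' @describeIn ParetoArchive-class Number of stored solutions.
#' @param x A `ParetoArchive`.
#' @export
setMethod("length", "ParetoArchive", function(x) nrow(x@objectives))

setMethod("show", "ParetoArchive", function(object) {
  cat(sprintf("ParetoArchive with %d / %d solutions (%d objectives)\n",
              nrow(object@objectives), as.integer(object@capacity),
              ncol(object@objectives)))
  if (nrow(object@objectives) > 0L) {
    rng <- apply(object@objectives, 2L, range)
    cat("objective ranges:\n")
    print(signif(rng, 4L))
  }
})

#' @rdname archiveObjectives
#' @export
setGeneric("archivePositions", function(x) standardGeneric("archivePositions"))

#' Archive accessors
#'
#' @param x A [ParetoArchive-class] (or an object containing one, e.g. a
#'   [FusionResult-class]).
#' @return `archivePositions`: matrix of decision vectors;
#'   `archiveObjectives`: matrix of objective vectors.
#' @export
setGeneric("archiveObjectives",
           function(x) standardGeneric("archiveObjectives"))

setMethod("archivePositions", "ParetoArchive", function(x) x@positions)
setMethod("archiveObjectives", "ParetoArchive", function(x) x@objectives)

#' FusionResult: output of the optimized fusion pipeline
#'
#' @slot fused Fused image (numeric matrix in `[0, 1]`).
#' @slot wt1,wt2 The nonnegative weight maps applied to each source.
#' @slot decision The selected decision vector (knee-point archive member).
#' @slot objectives Its `(Fitness1, cost)` objective vector.
#' @slot metrics Named list of quality metrics of the fused image.
#' @slot archive The final [ParetoArchive-class].
#' @slot trace Per-iteration run log (`data.frame`: iteration, hv,
#'   archiveSize, nKill, alpha).
#' @export
setClass("FusionResult",
         representation(fused = "matrix", wt1 = "matrix", wt2 = "matrix",
                        decision = "numeric", objectives = "numeric",
                        metrics = "list", archive = "ParetoArchive",
                        trace = "data.frame"))

setValidity("FusionResult", function(object) {
  if (!identical(dim(object@fused), dim(object@wt1)) ||
      !identical(dim(object@fused), dim(object@wt2)))
    return("fused image and weight maps must share one shape")
  if (any(object@wt1 < 0) || any(object@wt2 < 0))
    return("weight maps must be nonnegative")
  TRUE
})

setMethod("show", "FusionResult", function(object) {
  cat(sprintf("FusionResult: %d x %d fused image\n",
              nrow(object@fused), ncol(object@fused)))
  cat(sprintf("  decision: W1=%d W2=%d g=(%.3g, %.3g) gamma=(%.3g, %.3g)\n",
              c(3L, 5L, 7L, 9L)[round(object@decision[1L]) + 1L],
              c(3L, 5L, 7L, 9L)[round(object@decision[2L]) + 1L],
              object@decision[3L], object@decision[4L],
              object@decision[5L], object@decision[6L]))
  cat(sprintf("  Fitness1 = %.4f, cost = %.4g\n",
              object@objectives[1L], object@objectives[2L]))
  if (length(object@metrics))
    cat("  metrics:", paste(sprintf("%s=%.4f", names(object@metrics),
                                    unlist(object@metrics)),
                            collapse = ", "), "\n")
  cat(sprintf("  archive: %d solutions; %d iterations run\n",
              length(object@archive), nrow(object@trace)))
})

#' @rdname fusedImage
#' @export
setGeneric("fusedImage", function(x) standardGeneric("fusedImage"))

#' FusionResult accessors
#'
#' @param x A [FusionResult-class].
#' @return `fusedImage`: the fused raster; `fusionMetrics`: named list of
#'   quality metrics; `hvTrace`: per-iteration run log.
#' @name fusedImage
#' @export
setGeneric("fusionMetrics", function(x) standardGeneric("fusionMetrics"))

#' @rdname fusedImage
#' @export
setGeneric("hvTrace", function(x) standardGeneric("hvTrace"))

setMethod("fusedImage", "FusionResult", function(x) x@fused)
setMethod("fusionMetrics", "FusionResult", function(x) x@metrics)
setMethod("hvTrace", "FusionResult", function(x) x@trace)
setMethod("archivePositions", "FusionResult",
          function(x) x@archive@positions)
setMethod("archiveObjectives", "FusionResult",
          function(x) x@archive@objectives)

#' PhantomPair: a registered synthetic CT-like / MR-like image pair
#'
#' @slot ct,mr The two modality rasters in `[0, 1]`, one shape.
#' @slot masks Named list of logical masks sharing the image shape
#'   (`ring`, `brain`, `lesions`, `inserts`).
#' @slot seed The seed the pair was generated from.
#' @export
setClass("PhantomPair",
         representation(ct = "matrix", mr = "matrix", masks = "list",
                        seed = "numeric"))

setValidity("PhantomPair", function(object) {
  if (!identical(dim(object@ct), dim(object@mr)))
    return("ct and mr must share one shape")
  if (any(object@ct < 0 | object@ct > 1) || any(object@mr < 0 | object@mr > 1))
    return("phantom intensities must lie in [0, 1]")
  TRUE
})

setMethod("show", "PhantomPair", function(object) {
  cat(sprintf("PhantomPair: %d x %d (seed %d), masks: %s\n",
              nrow(object@ct), ncol(object@ct), as.integer(object@seed),
              paste(names(object@masks), collapse = ", ")))
})

#' @rdname phantomImages
#' @export
setGeneric("ctImage", function(x) standardGeneric("ctImage"))

#' PhantomPair accessors
#'
#' @param x A [PhantomPair-class].
#' @return The CT-like / MR-like raster, or the named list of masks.
#' @name phantomImages
#' @export
setGeneric("mrImage", function(x) standardGeneric("mrImage"))

#' @rdname phantomImages
#' @export
setGeneric("phantomMasks", function(x) standardGeneric("phantomMasks"))

setMethod("ctImage", "PhantomPair", function(x) x@ct)
setMethod("mrImage", "PhantomPair", function(x) x@mr)
setMethod("phantomMasks", "PhantomPair", function(x) x@masks)
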