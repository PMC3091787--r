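#' @rdname GenotypeCounts-class
#' @param x,object a `GenotypeCounts` object
#' @export
setGeneric("countsMatrix", function(x) standardGeneric("countsMatrix"))

#' @rdname GenotypeCounts-class
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname GenotypeCounts-class
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname GenotypeCounts-class
#' @export
setGeneric("nCalled", function(x) standardGeneric("nCalled"))

#' @rdname GenotypeCounts-class
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))

#' @describeIn GenotypeCounts-class the marker-by-class count matrix.
#' @export
setMethod("countsMatrix", "GenotypeCounts", function(x) x@counts)

#' @describeIn GenotypeCounts-class the aligned marker map `DataFrame`.
#' @export
setMethod("markerMap", "GenotypeCounts", function(x) x@map)

#' @describeIn GenotypeCounts-class marker identifiers.
#' @export
setMethod("markerNames", "GenotypeCounts", function(x) rownames(x@counts))

#' @describeIn GenotypeCounts-class per-marker number of successfully
#'   called samples (`nAA + nAB + nBB`).
#' @export
setMethod("nCalled", "GenotypeCounts", function(x)
    setNames(rowSums(x@counts[, c("nAA", "nAB", "nBB"), drop = FALSE]),
        rownames(x@counts)))

#' @describeIn GenotypeCounts-class per-marker total sample count
#'   including no-calls.
#' @export
setMethod("nTotal", "GenotypeCounts", function(x)
    setNames(rowSums(x@counts), rownames(x@counts)))

#' @describeIn GenotypeCounts-class subset markers by index, name or
#'   logical vector.
#' @param i marker index
#' @param j,...,drop ignored
#' @export
setMethod("[", "GenotypeCounts", function(x, i, j, ..., drop = FALSE) {
    new("GenotypeCounts", counts = x@counts[i, , drop = FALSE],
        map = x@map[i, , drop = FALSE])
})

#' @rdname ScenarioSpec-class
#' @param x a `ScenarioSpec`
#' @export
setGeneric("scenarioMarkers", function(x) standardGeneric("scenarioMarkers"))

#' @describeIn ScenarioSpec-class the per-marker truth table.
#' @export
setMethod("scenarioMarkers", "ScenarioSpec", function(x) x@markers)

#' @rdname ScenarioSpec-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @describeIn ScenarioSpec-class the number of simulated individuals.
#' @export
setMethod("nSamples", "ScenarioSpec", function(x) x@nSamples)
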