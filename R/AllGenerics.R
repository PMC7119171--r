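#' @include AllClasses.R
NULL

#' Accessors for panels, frequency tables and genotype matrices
#'
#' Small accessor generics used throughout the package:
#' `populationLabels()` and `sampleCounts()` read a panel's labels and
#' weights, `nPopulations()`/`nMarkers()` give dimensions,
#' `populationPanel()` extracts the attached [PopulationPanel-class],
#' `frequencies()` the markers x populations frequency matrix,
#' `markerInfo()` the marker metadata `DataFrame`, `genotypes()` the
#' markers x samples genotype matrix, `populations()` the per-sample
#' population factor, `scores()` per-marker scores, `scoreMethod()` the
#' scoring-method tag, and `ancestryProportions()` the Q matrix.
#'
#' @param x the object to access.
#' @return The corresponding component (see above).
#' @examples
#' panel <- PopulationPanel(c("CEU", "CHB", "YRI"))
#' populationLabels(panel)
#' nPopulations(panel)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("populationLabels", function(x) standardGeneric("populationLabels"))
#' @rdname accessors
#' @export
setGeneric("sampleCounts", function(x) standardGeneric("sampleCounts"))
#' @rdname accessors
#' @export
setGeneric("nPopulations", function(x) standardGeneric("nPopulations"))
#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname accessors
#' @export
setGeneric("populationPanel", function(x) standardGeneric("populationPanel"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("scoreMethod", function(x) standardGeneric("scoreMethod"))
#' @rdname accessors
#' @export
setGeneric("ancestryProportions", function(x)
    standardGeneric("ancestryProportions"))
#' @rdname accessors
#' @export
setGeneric("trueProportions", function(x) standardGeneric("trueProportions"))

#' @rdname lei
#' @export
setGeneric("lei", function(x, ...) standardGeneric("lei"))
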