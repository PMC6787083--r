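#' Accessors for cofgsea classes
#'
#' @param x an object.
#' @return `geneSets` returns the named list of member character vectors;
#'   `setDescriptions` the named description vector; `universe` the sorted
#'   union of all members (the "metabolic genes" denominator of the
#'   alternative enrichment); `cofactorGenes` the genes carrying any of the
#'   requested cofactor flags; `conditionLabel`, `dgeMethod` and
#'   `dgeRecords` the condition tag, DGE dialect and per-gene statistic
#'   table of a [DGETable].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname accessors
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname accessors
#' @param classes which cofactor classes to pool; any of `"coa"`,
#'   `"nadph_main"`, `"nadph_redox"`.
#' @export
setGeneric("cofactorGenes", function(x, classes = c("coa", "nadph_main"))
  standardGeneric("cofactorGenes"))

#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname accessors
#' @export
setGeneric("dgeMethod", function(x) standardGeneric("dgeMethod"))

#' @rdname accessors
#' @export
setGeneric("dgeRecords", function(x) standardGeneric("dgeRecords"))
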