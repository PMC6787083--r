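#' A planted enrichment signal for the synthetic generator
#'
#' Describes a directional expression shift applied to a fraction of one
#' gene set's members in a subset of conditions. Responsive members are
#' drawn once per signal (seeded), so the same genes respond in every
#' affected condition and in both DGE methods — the concordance the
#' median-rank aggregation is designed to detect.
#'
#' @slot targetSet name of the target gene set.
#' @slot direction `"up"` or `"down"`.
#' @slot responsiveFraction fraction of members shifted, in (0, 1].
#' @slot delta location shift of the t-statistic (dimensionless, >= 0).
#' @slot conditions affected condition labels; empty means all conditions.
#' @export
setClass("PlantedSignal",
         representation(targetSet = "character", direction = "character",
                        responsiveFraction = "numeric", delta = "numeric",
                        conditions = "character"))

setValidity("PlantedSignal", function(object) {
  msg <- character(0)
  if (length(object@targetSet) != 1L || is.na(object@targetSet))
    msg <- c(msg, "targetSet must be a single set name")
  if (length(object@direction) != 1L || !object@direction %in% c("up", "down"))
    msg <- c(msg, "direction must be 'up' or 'down'")
  rf <- object@responsiveFraction
  if (length(rf) != 1L || is.na(rf) || rf <= 0 || rf > 1)
    msg <- c(msg, "responsiveFraction must lie in (0, 1]")
  if (length(object@delta) != 1L || is.na(object@delta) || object@delta < 0)
    msg <- c(msg, "delta must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname PlantedSignal-class
#' @param targetSet,direction,responsiveFraction,delta,conditions see slots.
#' @return a [PlantedSignal-class] object.
#' @export
plantedSignal <- function(targetSet, direction = c("up", "down"),
                          responsiveFraction = 0.3, delta = 2,
                          conditions = character(0)) {
  direction <- match.arg(direction)
  new("PlantedSignal", targetSet = as.character(targetSet),
      direction = direction,
      responsiveFraction = as.numeric(responsiveFraction),
      delta = as.numeric(delta), conditions = as.character(conditions))
}

#' Specification of a synthetic multi-condition DGE study
#'
#' Defines the full fixture bundle: a gene universe with per-class cofactor
#' flags, an overlapping gene-set collection, and one DGE statistic table
#' per (condition x method), with optional planted signals. The bundle is a
#' pure function of the spec (including `seed`): identical specs yield
#' bitwise-identical output. Per-table random substreams are derived from
#' the seed by fixed offsets, so adding a condition or method never
#' perturbs previously generated tables.
#'
#' Defaults emulate a knockout-versus-wildtype liver transcriptome design:
#' four conditions (two diets x fed/fasted), two DGE dialects per
#' condition, ~10,000 expressed genes, 100 gene sets of 20-150 members
#' (typical metabolic-pathway sizes after restriction to a measured
#' transcriptome), and a Student-t(10) null for the ranking statistic
#' (roughly the residual degrees of freedom at 6-8 animals per group).
#'
#' @slot nGenes,nSets counts.
#' @slot setSizeRange integer pair, inclusive bounds on set sizes.
#' @slot cofactorFraction length-3 numeric: marginal fraction of CoA and
#'   NAD(P)(H)-main genes, and the conditional fraction of redox genes
#'   among main genes.
#' @slot nConditions number of conditions.
#' @slot conditionLabels condition labels.
#' @slot methods DGE dialect labels.
#' @slot planted list of [PlantedSignal-class].
#' @slot nullSigmaLfc standard deviation of null log2 fold changes.
#' @slot df degrees of freedom of the t-statistic noise model.
#' @slot seed integer seed.
#' @export
setClass("SimulationSpec",
         representation(nGenes = "integer", nSets = "integer",
                        setSizeRange = "integer", cofactorFraction = "numeric",
                        nConditions = "integer", conditionLabels = "character",
                        methods = "character", planted = "list",
                        nullSigmaLfc = "numeric", df = "numeric",
                        seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character(0)
  if (object@nGenes < 0L) msg <- c(msg, "nGenes must be >= 0")
  if (object@nSets < 0L) msg <- c(msg, "nSets must be >= 0")
  r <- object@setSizeRange
  if (length(r) != 2L || anyNA(r) || r[1] < 1L || r[2] < r[1])
    msg <- c(msg, "setSizeRange must be an increasing pair of positive counts")
  else if (object@nGenes > 0L && r[2] > object@nGenes)
    msg <- c(msg, "setSizeRange max must not exceed nGenes")
  f <- object@cofactorFraction
  if (length(f) != 3L || anyNA(f) || any(f < 0) || any(f > 1))
    msg <- c(msg, "cofactorFraction must be three proportions in [0, 1]")
  if (object@nConditions < 1L) msg <- c(msg, "nConditions must be >= 1")
  if (length(object@conditionLabels) != object@nConditions ||
      anyDuplicated(object@conditionLabels))
    msg <- c(msg, "conditionLabels must be nConditions unique labels")
  if (!length(object@methods) || anyDuplicated(object@methods) ||
      !all(object@methods %in% c("deseq2", "voom")))
    msg <- c(msg, "methods must be a non-empty subset of {deseq2, voom}")
  if (!all(vapply(object@planted, is, logical(1), "PlantedSignal")))
    msg <- c(msg, "planted must be a list of PlantedSignal objects")
  if (object@nullSigmaLfc <= 0) msg <- c(msg, "nullSigmaLfc must be > 0")
  if (object@df <= 0) msg <- c(msg, "df must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationSpec-class
#' @param nGenes,nSets,setSizeRange,nConditions,conditionLabels,methods,planted,nullSigmaLfc,df,seed
#'   see slots.
#' @param cofactorFraction either one proportion applied to every class, or
#'   a length-3 vector `(coa, nadph_main, nadph_redox-given-main)`.
#' @return a validated [SimulationSpec-class] object.
#' @examples
#' spec <- simulationSpec(nGenes = 500, nSets = 10, setSizeRange = c(5, 25),
#'                        seed = 7)
#' @export
simulationSpec <- function(nGenes = 10000, nSets = 100,
                           setSizeRange = c(20, 150), cofactorFraction = 0.1,
                           nConditions = 4,
                           conditionLabels = c("LF_fed", "LF_fasted",
                                               "HF_fed", "HF_fasted"),
                           methods = c("deseq2", "voom"), planted = list(),
                           nullSigmaLfc = 0.4, df = 10, seed = 1) {
  if (length(cofactorFraction) == 1L)
    cofactorFraction <- rep(cofactorFraction, 3L)
  if (nConditions != 4 && identical(conditionLabels,
                                    c("LF_fed", "LF_fasted", "HF_fed", "HF_fasted")))
    conditionLabels <- sprintf("condition%02d", seq_len(nConditions))
  new("SimulationSpec", nGenes = as.integer(nGenes), nSets = as.integer(nSets),
      setSizeRange = as.integer(setSizeRange),
      cofactorFraction = as.numeric(cofactorFraction),
      nConditions = as.integer(nConditions),
      conditionLabels = as.character(conditionLabels),
      methods = as.character(methods), planted = planted,
      nullSigmaLfc = as.numeric(nullSigmaLfc), df = as.numeric(df),
      seed = as.integer(seed))
}

#' @export
setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(paste0("SimulationSpec: %d genes, %d sets [%d-%d], ",
                     "%d condition(s) x {%s}, %d planted signal(s), seed %d\n"),
              object@nGenes, object@nSets, object@setSizeRange[1],
              object@setSizeRange[2], object@nConditions,
              paste(object@methods, collapse = ","), length(object@planted),
              object@seed))
})

#' Configuration of the pre-ranked GSEA
#'
#' Defaults follow common pre-ranked GSEA practice: weighted enrichment
#' statistic (exponent 1 on the absolute ranking score), 1000 gene-set
#' permutations, set-size filter 15-500, and the two reporting tiers
#' FDR < 0.05 (significant) and FDR < 0.25 (explorative).
#'
#' @slot weightExponent exponent on the absolute ranking score.
#' @slot nPermutations number of random same-size gene sets per set.
#' @slot minSetSize,maxSetSize inclusive size filter applied after
#'   restriction to the ranked universe.
#' @slot seed integer seed for the permutation stream.
#' @slot fdrExplorative,fdrSignificant reporting thresholds.
#' @export
setClass("GseaConfig",
         representation(weightExponent = "numeric", nPermutations = "integer",
                        minSetSize = "numeric", maxSetSize = "numeric",
                        seed = "integer", fdrExplorative = "numeric",
                        fdrSignificant = "numeric"))

setValidity("GseaConfig", function(object) {
  msg <- character(0)
  if (object@nPermutations < 1L) msg <- c(msg, "nPermutations must be >= 1")
  if (object@minSetSize < 1 || object@maxSetSize < object@minSetSize)
    msg <- c(msg, "set size filter must satisfy 1 <= min <= max")
  for (fl in c("fdrExplorative", "fdrSignificant")) {
    v <- slot(object, fl)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", fl))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GseaConfig-class
#' @param weightExponent,nPermutations,minSetSize,maxSetSize,seed,fdrExplorative,fdrSignificant
#'   see slots.
#' @return a validated [GseaConfig-class] object.
#' @export
gseaConfig <- function(weightExponent = 1, nPermutations = 1000,
                       minSetSize = 15, maxSetSize = 500, seed = 1,
                       fdrExplorative = 0.25, fdrSignificant = 0.05) {
  new("GseaConfig", weightExponent = as.numeric(weightExponent),
      nPermutations = as.integer(nPermutations),
      minSetSize = as.numeric(minSetSize), maxSetSize = as.numeric(maxSetSize),
      seed = as.integer(seed), fdrExplorative = as.numeric(fdrExplorative),
      fdrSignificant = as.numeric(fdrSignificant))
}

#' @export
setMethod("show", "GseaConfig", function(object) {
  cat(sprintf(paste0("GseaConfig: weight %g, %d permutations, sizes [%g, %g], ",
                     "FDR tiers %g/%g, seed %d\n"),
              object@weightExponent, object@nPermutations, object@minSetSize,
              object@maxSetSize, object@fdrSignificant, object@fdrExplorative,
              object@seed))
})
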