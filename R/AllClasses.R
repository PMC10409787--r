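#' @include AllGenerics.R
NULL

#' @importFrom methods setClass setValidity validObject new is slot
#' @importFrom methods setMethod setGeneric show callNextMethod as
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

## ---------------------------------------------------------------------------
## AbundanceTable
## ---------------------------------------------------------------------------

#' Genome-by-sample relative abundance table
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' single assay `"relabund"` of per-sample relative abundances (fractions in
#' `[0, 1]`). Rows are genomes (MAGs), columns are samples (metagenomes).
#' Per-sample totals may be below 1 (unmapped reads) but never exceed
#' `1 + 1e-6`.
#'
#' @param values Numeric matrix of abundances with genome row names and sample
#'   column names. Interpreted according to `unit`.
#' @param unit Either `"fraction"` (values already in `[0, 1]`) or `"percent"`
#'   (values in `[0, 100]`, divided by 100 on construction).
#' @return An `AbundanceTable`.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0, 1), 2, dimnames = list(c("gA", "gB"), c("s1", "s2")))
#' AbundanceTable(m)
#' @export
#' @aliases AbundanceTable-class
setClass("AbundanceTable", contains = "SummarizedExperiment")

#' @rdname AbundanceTable-class
#' @export
AbundanceTable <- function(values, unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have genome row names and sample column names")
  if (unit == "percent") values <- values / 100
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(relabund = values))
  new("AbundanceTable", se)
}

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (!"relabund" %in% SummarizedExperiment::assayNames(object))
    return("assay 'relabund' is missing")
  v <- SummarizedExperiment::assay(object, "relabund")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "abundances must be finite and non-missing")
  else {
    if (any(v < 0)) msg <- c(msg, "abundances must be non-negative")
    cs <- colSums(v)
    if (length(cs) && any(cs > 1 + 1e-6))
      msg <- c(msg, sprintf("column sum exceeds 1 (sample '%s': %.6g)",
                            colnames(v)[which.max(cs)], max(cs)))
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate genome_id '%s'",
                          rownames(object)[duplicated(rownames(object))][1L]))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicate sample_id '%s'",
                          colnames(object)[duplicated(colnames(object))][1L]))
  if (length(msg)) msg else TRUE
})

#' @rdname abundances
#' @export
setMethod("abundances", "AbundanceTable", function(x)
  SummarizedExperiment::assay(x, "relabund"))

#' @rdname genomeIds
#' @export
setMethod("genomeIds", "AbundanceTable", function(x) rownames(x))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "AbundanceTable", function(x) colnames(x))

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d genomes x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  per-sample totals: %.3f-%.3f\n",
              min(colSums(abundances(object))),
              max(colSums(abundances(object)))))
})

## ---------------------------------------------------------------------------
## SampleMetadata
## ---------------------------------------------------------------------------

#' Per-sample condition metadata
#'
#' A [S4Vectors::DataFrame] keyed by sample id (row names) with the two
#' condition axes used for stratified comparisons: `lifestyle`
#' (`"biofilm"`/`"planktonic"`) and `scn_level` (`"high"`/`"low"` thiocyanate).
#' Additional columns are carried through untouched.
#'
#' @param df A data.frame or DataFrame with row names (or a `sample_id`
#'   column) and columns `lifestyle` and `scn_level`.
#' @return A `SampleMetadata`.
#' @export
#' @aliases SampleMetadata-class
setClass("SampleMetadata", contains = "DFrame")

#' @rdname SampleMetadata-class
#' @export
SampleMetadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if ("sample_id" %in% colnames(df)) {
    rownames(df) <- df$sample_id
    df$sample_id <- NULL
  }
  new("SampleMetadata", S4Vectors::DataFrame(df, check.names = FALSE))
}

.lifestyleVocab <- c("biofilm", "planktonic")
.scnVocab <- c("high", "low")

setValidity("SampleMetadata", function(object) {
  msg <- character()
  if (is.null(rownames(object)))
    msg <- c(msg, "sample ids (row names) are required")
  else if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate sample_id '%s'",
                          rownames(object)[duplicated(rownames(object))][1L]))
  for (col in c("lifestyle", "scn_level")) {
    if (!col %in% colnames(object)) {
      msg <- c(msg, sprintf("column '%s' is required", col))
      next
    }
    vocab <- if (col == "lifestyle") .lifestyleVocab else .scnVocab
    vals <- as.character(object[[col]])
    bad <- setdiff(unique(vals[!is.na(vals)]), vocab)
    if (length(bad))
      msg <- c(msg, sprintf("invalid %s value '%s' (allowed: %s)",
                            col, bad[1L], paste(vocab, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SampleMetadata", function(x) rownames(x))

## ---------------------------------------------------------------------------
## AnnotationSet
## ---------------------------------------------------------------------------

#' Per-genome KEGG ortholog annotations and genome lengths
#'
#' Holds a deduplicated KO set per genome (a named
#' [IRanges::CharacterList]) and genome lengths in bp. A genome may have an
#' empty KO set; a genome without a known length carries `NA` and is excluded
#' from genome-size analyses only.
#'
#' @param ko Named list (or CharacterList) of KO identifier vectors, one per
#'   genome. Identifiers must match `K\\d{5}`.
#' @param lengths Named numeric vector of genome lengths in bp (`NA` allowed);
#'   names not in `ko` are added with empty KO sets.
#' @return An `AnnotationSet`.
#' @export
#' @aliases AnnotationSet-class
setClass("AnnotationSet",
         representation(ko = "CharacterList", genomeLength = "numeric"))

#' @rdname AnnotationSet-class
#' @export
AnnotationSet <- function(ko, lengths = numeric()) {
  ko <- lapply(ko, function(k) sort(unique(as.character(k))))
  extra <- setdiff(names(lengths), names(ko))
  if (length(extra))
    ko[extra] <- list(character())
  len <- rep(NA_real_, length(ko))
  names(len) <- names(ko)
  common <- intersect(names(lengths), names(ko))
  len[common] <- as.numeric(lengths[common])
  new("AnnotationSet", ko = IRanges::CharacterList(ko), genomeLength = len)
}

setValidity("AnnotationSet", function(object) {
  msg <- character()
  kos <- unlist(object@ko, use.names = FALSE)
  bad <- kos[!grepl("^K[0-9]{5}$", kos)]
  if (length(bad))
    msg <- c(msg, sprintf("malformed KO id '%s'", bad[1L]))
  if (is.null(names(object@ko)) || anyDuplicated(names(object@ko)))
    msg <- c(msg, "genome ids must be unique and named")
  if (!identical(names(object@genomeLength), names(object@ko)))
    msg <- c(msg, "length vector must be named by the same genomes")
  ln <- object@genomeLength
  if (any(!is.na(ln) & ln <= 0))
    msg <- c(msg, "genome lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname koSets
#' @export
setMethod("koSets", "AnnotationSet", function(x) x@ko)

#' @rdname genomeLengths
#' @export
setMethod("genomeLengths", "AnnotationSet", function(x) x@genomeLength)

#' @rdname genomeIds
#' @export
setMethod("genomeIds", "AnnotationSet", function(x) names(x@ko))

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d genomes, %d distinct KOs, %d with length\n",
              length(object@ko),
              length(unique(unlist(object@ko, use.names = FALSE))),
              sum(!is.na(object@genomeLength))))
})

## ---------------------------------------------------------------------------
## PathwayCatalog
## ---------------------------------------------------------------------------

#' Vitamin biosynthesis pathway definitions
#'
#' Config-style catalog: for each vitamin an ordered list of stages, each
#' stage a set of alternative KOs any one of which satisfies the stage, plus a
#' set of exempt KOs whose sole absence still yields a near-complete call
#' (for thiamine: thiC, K03147).
#'
#' @param vitamins Named list; each element is
#'   `list(stages = list(<stage name> = <character KOs>, ...), exempt = <character>)`.
#' @return A `PathwayCatalog`.
#' @seealso [defaultPathwayCatalog()], [readPathwayCatalog()]
#' @export
#' @aliases PathwayCatalog-class
setClass("PathwayCatalog", representation(vitamins = "list"))

#' @rdname PathwayCatalog-class
#' @export
PathwayCatalog <- function(vitamins) {
  vitamins <- lapply(vitamins, function(v) {
    stages <- lapply(v$stages, as.character)
    exempt <- if (is.null(v$exempt)) character() else as.character(v$exempt)
    list(stages = stages, exempt = exempt)
  })
  new("PathwayCatalog", vitamins = vitamins)
}

setValidity("PathwayCatalog", function(object) {
  msg <- character()
  vs <- object@vitamins
  if (is.null(names(vs)) || anyDuplicated(names(vs)))
    msg <- c(msg, "vitamin names must be unique")
  for (vn in names(vs)) {
    v <- vs[[vn]]
    if (!length(v$stages))
      msg <- c(msg, sprintf("vitamin '%s' has no stages", vn))
    if (is.null(names(v$stages)) || anyDuplicated(names(v$stages)))
      msg <- c(msg, sprintf("vitamin '%s' stage names must be unique", vn))
    if (any(!lengths(v$stages)))
      msg <- c(msg, sprintf("vitamin '%s' has a stage with no KOs", vn))
    allko <- unlist(v$stages, use.names = FALSE)
    if (length(setdiff(v$exempt, allko)))
      msg <- c(msg, sprintf(
        "vitamin '%s': exempt KOs must be a subset of the stage KOs", vn))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname vitaminNames
#' @export
setMethod("vitaminNames", "PathwayCatalog", function(x) names(x@vitamins))

#' Stage definitions for one vitamin
#'
#' @param cat A [PathwayCatalog].
#' @param vitamin Vitamin name.
#' @return Named list of character KO vectors (one per stage).
#' @export
pathwayStages <- function(cat, vitamin) {
  stopifnot(is(cat, "PathwayCatalog"))
  if (!vitamin %in% names(cat@vitamins))
    stop(sprintf("unknown vitamin '%s'", vitamin))
  cat@vitamins[[vitamin]]$stages
}

#' Exempt KOs for one vitamin
#'
#' KOs whose sole absence leaves a pathway near-complete rather than absent.
#'
#' @inheritParams pathwayStages
#' @return Character vector (possibly empty).
#' @export
exemptKos <- function(cat, vitamin) {
  stopifnot(is(cat, "PathwayCatalog"))
  if (!vitamin %in% names(cat@vitamins))
    stop(sprintf("unknown vitamin '%s'", vitamin))
  cat@vitamins[[vitamin]]$exempt
}

setMethod("show", "PathwayCatalog", function(object) {
  cat(sprintf("PathwayCatalog: %d vitamins\n", length(object@vitamins)))
  for (vn in names(object@vitamins))
    cat(sprintf("  %s: %d stages, %d exempt KOs\n", vn,
                length(object@vitamins[[vn]]$stages),
                length(object@vitamins[[vn]]$exempt)))
})

## ---------------------------------------------------------------------------
## CorrelationMatrix
## ---------------------------------------------------------------------------

#' Pairwise genome correlation matrix
#'
#' Symmetric correlations in `[-1, 1]` with unit diagonal, optionally with a
#' companion matrix of permutation p-values.
#'
#' @param r Symmetric numeric matrix with genome ids as dimnames.
#' @param p Optional symmetric matrix of p-values in `[0, 1]`.
#' @return A `CorrelationMatrix`.
#' @export
#' @aliases CorrelationMatrix-class
setClass("CorrelationMatrix",
         representation(r = "matrix", p = "matrixOrNULL"))

#' @rdname CorrelationMatrix-class
#' @export
CorrelationMatrix <- function(r, p = NULL) {
  new("CorrelationMatrix", r = r, p = p)
}

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  r <- object@r
  if (nrow(r) != ncol(r)) return("correlation matrix must be square")
  if (is.null(rownames(r)) || !identical(rownames(r), colnames(r)))
    msg <- c(msg, "dimnames must be identical genome ids")
  if (anyNA(r)) msg <- c(msg, "correlations must not be missing")
  else {
    if (max(abs(r - t(r))) > 0)
      msg <- c(msg, "correlation matrix must be exactly symmetric")
    if (any(abs(diag(r) - 1) > 0))
      msg <- c(msg, "diagonal must be exactly 1")
    if (any(r < -1) || any(r > 1))
      msg <- c(msg, "correlations must lie in [-1, 1]")
  }
  if (!is.null(object@p)) {
    p <- object@p
    if (!identical(dim(p), dim(r)))
      msg <- c(msg, "p-value matrix must match the correlation matrix")
    else if (any(p < 0, na.rm = TRUE) || any(p > 1, na.rm = TRUE))
      msg <- c(msg, "p-values must lie in [0, 1]")
    else if (max(abs(p - t(p)), na.rm = TRUE) > 0)
      msg <- c(msg, "p-value matrix must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname correlations
#' @export
setMethod("correlations", "CorrelationMatrix", function(x) x@r)

#' @rdname pvalues
#' @export
setMethod("pvalues", "CorrelationMatrix", function(x) x@p)

#' @rdname genomeIds
#' @export
setMethod("genomeIds", "CorrelationMatrix", function(x) rownames(x@r))

setMethod("show", "CorrelationMatrix", function(object) {
  off <- object@r[upper.tri(object@r)]
  cat(sprintf("CorrelationMatrix: %d genomes%s\n", nrow(object@r),
              if (is.null(object@p)) "" else " (with p-values)"))
  if (length(off))
    cat(sprintf("  off-diagonal r: median %.3f, range [%.3f, %.3f]\n",
                stats::median(off), min(off), max(off)))
})

## ---------------------------------------------------------------------------
## SparccParams
## ---------------------------------------------------------------------------

#' Parameters of the SparCC-style basis correlation estimator
#'
#' @param nIterations Outer estimation rounds; round 1 uses the observed
#'   compositions, later rounds Dirichlet-resample them, and the estimate is
#'   the element-wise median. `1` gives the single deterministic estimate.
#' @param exclusionThreshold Correlation magnitude above which the
#'   most-correlated pair is excluded from basis-variance estimation.
#' @param pseudocount Small positive fraction added before the log transform
#'   so zero abundances are representable.
#' @param nExclusionRounds Maximum number of strongly-correlated pairs to
#'   exclude per round.
#' @param resampleDepth Concentration scale of the Dirichlet resampling
#'   (plays the role of a per-sample count depth for fraction-only input).
#' @return A `SparccParams` object.
#' @export
#' @aliases SparccParams-class
setClass("SparccParams",
         representation(nIterations = "integer",
                        exclusionThreshold = "numeric",
                        pseudocount = "numeric",
                        nExclusionRounds = "integer",
                        resampleDepth = "numeric"))

#' @rdname SparccParams-class
#' @export
SparccParams <- function(nIterations = 20L, exclusionThreshold = 0.1,
                         pseudocount = 1e-6, nExclusionRounds = 10L,
                         resampleDepth = 1000) {
  new("SparccParams",
      nIterations = as.integer(nIterations),
      exclusionThreshold = exclusionThreshold,
      pseudocount = pseudocount,
      nExclusionRounds = as.integer(nExclusionRounds),
      resampleDepth = resampleDepth)
}

setValidity("SparccParams", function(object) {
  msg <- character()
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (object@exclusionThreshold <= 0 || object@exclusionThreshold >= 1)
    msg <- c(msg, "exclusionThreshold must lie in (0, 1)")
  if (object@pseudocount <= 0) msg <- c(msg, "pseudocount must be positive")
  if (object@nExclusionRounds < 0L)
    msg <- c(msg, "nExclusionRounds must be non-negative")
  if (object@resampleDepth <= 0) msg <- c(msg, "resampleDepth must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CooccurrenceNetwork
## ---------------------------------------------------------------------------

#' Thresholded co-occurrence network
#'
#' Undirected simple graph over genomes; each edge is a retained correlation
#' (weight = r). Genomes with no retained edge are not part of the network;
#' their ids are kept in the `dropped` slot.
#'
#' @param graph An igraph graph with vertex `name` and edge `weight`.
#' @param threshold Correlation threshold used at construction.
#' @param positiveOnly Whether only positive correlations were retained.
#' @param dropped Genome ids excluded for having no retained edge.
#' @return A `CooccurrenceNetwork`.
#' @seealso [buildNetwork()]
#' @export
#' @aliases CooccurrenceNetwork-class
setClass("CooccurrenceNetwork",
         representation(graph = "ANY", threshold = "numeric",
                        positiveOnly = "logical", dropped = "character"))

#' @rdname CooccurrenceNetwork-class
#' @export
CooccurrenceNetwork <- function(graph, threshold, positiveOnly = TRUE,
                                dropped = character()) {
  new("CooccurrenceNetwork", graph = graph, threshold = threshold,
      positiveOnly = positiveOnly, dropped = dropped)
}

setValidity("CooccurrenceNetwork", function(object) {
  msg <- character()
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    msg <- c(msg, "vertices must be named")
  if (igraph::ecount(g) > 0) {
    if (is.null(igraph::E(g)$weight))
      msg <- c(msg, "edges must carry correlation weights")
    else if (object@positiveOnly &&
             any(igraph::E(g)$weight < object@threshold))
      msg <- c(msg, "every edge weight must be >= the construction threshold")
    if (any(igraph::which_loop(g)))
      msg <- c(msg, "self-loops are not allowed")
    if (any(igraph::which_multiple(g)))
      msg <- c(msg, "parallel edges are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "CooccurrenceNetwork", function(x) x@graph)

#' @rdname genomeIds
#' @export
setMethod("genomeIds", "CooccurrenceNetwork", function(x) {
  if (igraph::vcount(x@graph) == 0) character() else igraph::V(x@graph)$name
})

#' Number of nodes / edges of a network
#'
#' @param net A [CooccurrenceNetwork].
#' @return Integer count.
#' @export
numNodes <- function(net) igraph::vcount(networkGraph(net))

#' @rdname numNodes
#' @export
numEdges <- function(net) igraph::ecount(networkGraph(net))

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat(sprintf(
    "CooccurrenceNetwork: %d nodes, %d edges (r >= %.2f%s; %d genomes dropped)\n",
    numNodes(object), numEdges(object), object@threshold,
    if (object@positiveOnly) ", positive only" else "",
    length(object@dropped)))
})

## ---------------------------------------------------------------------------
## NetworkPartition / NetworkSummary
## ---------------------------------------------------------------------------

#' Module partition of a network
#'
#' @slot membership Named integer vector: node -> module id.
#' @slot modularity Weighted modularity Q of the partition.
#' @slot method `"louvain"` or `"girvan_newman"`.
#' @slot seed Seed used for tie-breaking.
#' @seealso [detectModules()]
#' @export
#' @aliases NetworkPartition-class
setClass("NetworkPartition",
         representation(membership = "integer", modularity = "numeric",
                        method = "character", seed = "integer"))

setValidity("NetworkPartition", function(object) {
  msg <- character()
  if (is.null(names(object@membership)))
    msg <- c(msg, "membership must be named by node")
  if (anyNA(object@membership))
    msg <- c(msg, "every node must be assigned exactly one module")
  if (length(object@modularity) != 1 ||
      object@modularity < -0.5 - 1e-12 || object@modularity > 1 + 1e-12)
    msg <- c(msg, "modularity must lie in [-0.5, 1]")
  if (!object@method %in% c("louvain", "girvan_newman"))
    msg <- c(msg, "method must be 'louvain' or 'girvan_newman'")
  if (length(msg)) msg else TRUE
})

#' Module membership vector
#'
#' @param part A [NetworkPartition].
#' @return Named integer vector mapping node to module id.
#' @export
moduleMembership <- function(part) {
  stopifnot(is(part, "NetworkPartition"))
  part@membership
}

#' Modularity of a partition
#'
#' @param part A [NetworkPartition].
#' @return Numeric Q.
#' @export
partitionModularity <- function(part) {
  stopifnot(is(part, "NetworkPartition"))
  part@modularity
}

setMethod("show", "NetworkPartition", function(object) {
  cat(sprintf("NetworkPartition (%s): %d modules over %d nodes, Q = %.3f\n",
              object@method, length(unique(object@membership)),
              length(object@membership), object@modularity))
})

#' Whole-network summary statistics
#'
#' Node and edge counts, density `d = 2m / (n (n - 1))`, mean degree `2m / n`
#' and the modularity of the supplied partition.
#'
#' @seealso [networkSummary()]
#' @export
#' @aliases NetworkSummary-class
setClass("NetworkSummary",
         representation(nNodes = "integer", nEdges = "integer",
                        density = "numeric", meanDegree = "numeric",
                        modularity = "numeric"))

setMethod("show", "NetworkSummary", function(object) {
  cat(sprintf(
    "NetworkSummary: n = %d, m = %d, density = %.4f (%.1f%%), mean degree = %.2f, Q = %s\n",
    object@nNodes, object@nEdges, object@density, 100 * object@density,
    object@meanDegree,
    if (is.na(object@modularity)) "NA" else sprintf("%.3f", object@modularity)))
})

## ---------------------------------------------------------------------------
## CapabilityCall / RoleLabels
## ---------------------------------------------------------------------------

#' Per-genome, per-vitamin pathway completeness call
#'
#' `status` is `"complete"` (every stage satisfied), `"near_complete"` (the
#' only missing KOs all lie in the catalog's exempt set) or `"absent"`.
#'
#' @seealso [callPathway()]
#' @export
#' @aliases CapabilityCall-class
setClass("CapabilityCall",
         representation(genomeId = "character", vitamin = "character",
                        status = "character", satisfiedStages = "character",
                        missingKos = "character"))

setValidity("CapabilityCall", function(object) {
  if (!object@status %in% c("complete", "near_complete", "absent"))
    "status must be complete, near_complete or absent" else TRUE
})

#' Status of a capability call
#'
#' @param call A [CapabilityCall].
#' @return One of `"complete"`, `"near_complete"`, `"absent"`.
#' @export
callStatus <- function(call) {
  stopifnot(is(call, "CapabilityCall"))
  call@status
}

#' Missing KOs of a capability call
#'
#' @param call A [CapabilityCall].
#' @return Character vector of KOs from unsatisfied stages.
#' @export
missingKos <- function(call) {
  stopifnot(is(call, "CapabilityCall"))
  call@missingKos
}

setMethod("show", "CapabilityCall", function(object) {
  cat(sprintf("CapabilityCall: %s / %s -> %s\n", object@genomeId,
              object@vitamin, object@status))
  if (length(object@missingKos))
    cat(sprintf("  missing KOs: %s\n", paste(object@missingKos, collapse = ", ")))
})

#' Producer/auxotroph role labels for one vitamin
#'
#' @seealso [classifyRoles()]
#' @export
#' @aliases RoleLabels-class
setClass("RoleLabels",
         representation(vitamin = "character", roleVec = "character",
                        policy = "character"))

setValidity("RoleLabels", function(object) {
  msg <- character()
  if (length(object@roleVec)) {
    if (is.null(names(object@roleVec)))
      msg <- c(msg, "roles must be named by genome")
    if (!all(object@roleVec %in% c("producer", "auxotroph")))
      msg <- c(msg, "roles must be 'producer' or 'auxotroph'")
    if (anyDuplicated(names(object@roleVec)))
      msg <- c(msg, "duplicate genome in roles")
  }
  if (!object@policy %in% c("producer", "auxotroph"))
    msg <- c(msg, "near-complete policy must be 'producer' or 'auxotroph'")
  if (length(msg)) msg else TRUE
})

#' @rdname roles
#' @export
setMethod("roles", "RoleLabels", function(x) x@roleVec)

#' @rdname nProducers
#' @export
setMethod("nProducers", "RoleLabels", function(x)
  sum(x@roleVec == "producer"))

#' @rdname nAuxotrophs
#' @export
setMethod("nAuxotrophs", "RoleLabels", function(x)
  sum(x@roleVec == "auxotroph"))

setMethod("show", "RoleLabels", function(object) {
  cat(sprintf(
    "RoleLabels (%s): %d producers, %d auxotrophs (near-complete policy: %s)\n",
    object@vitamin, nProducers(object), nAuxotrophs(object), object@policy))
})

## ---------------------------------------------------------------------------
## HubnessScore / NullDistribution
## ---------------------------------------------------------------------------

#' Vitamin-hubness score of one node
#'
#' For a producer v with at least one auxotroph neighbor,
#' `h = (dTotal * dAuxotroph) / denom` where `denom` is the mean number of
#' producer-labeled nodes adjacent to each of v's auxotroph neighbors
#' (v itself included). With no auxotroph neighbors `h = 0`.
#'
#' @seealso [hubScore()]
#' @export
#' @aliases HubnessScore-class
setClass("HubnessScore",
         representation(node = "character", dTotal = "integer",
                        dAuxotroph = "integer", producerLinks = "numeric",
                        denom = "numeric", score = "numeric"))

#' Numeric value of a hubness score
#'
#' @param x A [HubnessScore].
#' @return Numeric h.
#' @export
scoreValue <- function(x) {
  stopifnot(is(x, "HubnessScore"))
  x@score
}

setMethod("show", "HubnessScore", function(object) {
  cat(sprintf(
    "HubnessScore: %s  h = %.3f  (degree = %d, auxotroph neighbors = %d, mean producer links = %s)\n",
    object@node, object@score, object@dTotal, object@dAuxotroph,
    if (is.na(object@denom)) "NA" else sprintf("%.3f", object@denom)))
})

#' Label-randomization null distribution of a hubness score
#'
#' Each simulation redraws a producer set of the observed size uniformly at
#' random, relabels all other nodes auxotroph, and recomputes the focal
#' node's score.
#'
#' @seealso [randomizationNull()]
#' @export
#' @aliases NullDistribution-class
setClass("NullDistribution",
         representation(focal = "character", nSim = "integer",
                        seed = "integer", focalPolicy = "character",
                        scores = "numeric", nullMean = "numeric",
                        nullSd = "numeric", z = "numeric",
                        empiricalP = "numeric", observed = "numeric",
                        nIllDefined = "integer"))

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (length(object@scores) != object@nSim)
    msg <- c(msg, "scores must have one entry per simulation")
  if (!object@focalPolicy %in% c("focal_forced_producer", "free_relabel"))
    msg <- c(msg, "focalPolicy must be 'focal_forced_producer' or 'free_relabel'")
  if (length(msg)) msg else TRUE
})

#' Simulated scores of a null distribution
#'
#' @param x A [NullDistribution].
#' @return Numeric vector of length `nSim`.
#' @export
nullScores <- function(x) {
  stopifnot(is(x, "NullDistribution"))
  x@scores
}

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution (%s): focal %s, %d simulations\n  observed h = %.2f, null mean = %.2f, sd = %.2f, z = %s, empirical p = %.4g\n",
    object@focalPolicy, object@focal, object@nSim, object@observed,
    object@nullMean, object@nullSd,
    if (is.na(object@z)) "NA" else sprintf("%.2f", object@z),
    object@empiricalP))
  if (object@nIllDefined > 0)
    cat(sprintf("  %d ill-defined draws recorded as h = 0\n",
                object@nIllDefined))
})

## ---------------------------------------------------------------------------
## SyntheticSpec / SyntheticTruth
## ---------------------------------------------------------------------------

#' Specification of a synthetic bioreactor community
#'
#' Defaults emulate the structure the analysis targets: 120 genomes across 92
#' samples organised into 4 correlated modules of 30, a planted
#' vitamin-producer hub in module 1 whose 8 dependent neighbors are thiamine
#' auxotrophs, and 38 thiamine producers overall.
#'
#' @param nGenomes Number of genomes.
#' @param nSamples Number of samples (metagenomes).
#' @param moduleSizes Integer vector of module sizes (sum must not exceed
#'   `nGenomes`; remaining genomes form uncorrelated background).
#' @param rhoIn Within-module basis correlation of log abundances.
#' @param rhoOut Between-module basis correlation.
#' @param hubModule Module index holding the planted hub.
#' @param nDependents Number of hub-dependent auxotrophs (module mates whose
#'   correlation with the hub is raised to `rhoHub`).
#' @param rhoHub Hub-to-dependent basis correlation.
#' @param hubVitamin Vitamin for which the hub phenotype is planted.
#' @param producerFractions Named fractions of genomes that are producers per
#'   vitamin (counts are `round(fraction * nGenomes)`).
#' @param nearCompleteFraction Fraction of producers (per vitamin with a
#'   non-empty exempt set) planted as near-complete rather than complete.
#' @param logMu,logSigma Lognormal basis parameters of latent abundances.
#' @param depth Multinomial sequencing depth per sample.
#' @param metadataEffect Multiplicative per-module abundance shift between
#'   condition categories (see the methods vignette).
#' @param seed Default seed for [simulateCommunity()].
#' @return A `SyntheticSpec`.
#' @export
#' @aliases SyntheticSpec-class
setClass("SyntheticSpec",
         representation(nGenomes = "integer", nSamples = "integer",
                        moduleSizes = "integer", rhoIn = "numeric",
                        rhoOut = "numeric", hubModule = "integer",
                        nDependents = "integer", rhoHub = "numeric",
                        hubVitamin = "character",
                        producerFractions = "numeric",
                        nearCompleteFraction = "numeric",
                        logMu = "numeric", logSigma = "numeric",
                        depth = "numeric", metadataEffect = "numeric",
                        seed = "integer"))

#' @rdname SyntheticSpec-class
#' @export
SyntheticSpec <- function(nGenomes = 120L, nSamples = 92L,
                          moduleSizes = rep(30L, 4L),
                          rhoIn = 0.7, rhoOut = 0,
                          hubModule = 1L, nDependents = 8L, rhoHub = 0.8,
                          hubVitamin = "thiamine",
                          producerFractions = c(thiamine = 38 / 120,
                                                biotin = 0.45,
                                                tetrahydrofolate = 0.60,
                                                riboflavin = 0.55,
                                                NAD = 0.70,
                                                pantothenate = 0.35),
                          nearCompleteFraction = 0.1,
                          logMu = 0, logSigma = 1,
                          depth = 1e5, metadataEffect = 2,
                          seed = 1L) {
  new("SyntheticSpec",
      nGenomes = as.integer(nGenomes), nSamples = as.integer(nSamples),
      moduleSizes = as.integer(moduleSizes), rhoIn = rhoIn, rhoOut = rhoOut,
      hubModule = as.integer(hubModule), nDependents = as.integer(nDependents),
      rhoHub = rhoHub, hubVitamin = hubVitamin,
      producerFractions = producerFractions,
      nearCompleteFraction = nearCompleteFraction,
      logMu = logMu, logSigma = logSigma, depth = depth,
      metadataEffect = metadataEffect, seed = as.integer(seed))
}

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (sum(object@moduleSizes) > object@nGenomes)
    msg <- c(msg, "module sizes must sum to at most nGenomes")
  rho <- c(object@rhoIn, object@rhoOut, object@rhoHub)
  if (any(rho < 0) || any(rho >= 1))
    msg <- c(msg, "all correlations must lie in [0, 1)")
  pf <- object@producerFractions
  if (is.null(names(pf)) || any(pf < 0) || any(pf > 1))
    msg <- c(msg, "producerFractions must be named fractions in [0, 1]")
  if (!object@hubVitamin %in% names(pf))
    msg <- c(msg, "hubVitamin must appear in producerFractions")
  if (object@hubModule < 1L || object@hubModule > length(object@moduleSizes))
    msg <- c(msg, "hubModule must index an existing module")
  if (object@nDependents >= object@moduleSizes[object@hubModule])
    msg <- c(msg, "nDependents must be smaller than the hub module")
  if (object@nearCompleteFraction < 0 || object@nearCompleteFraction > 1)
    msg <- c(msg, "nearCompleteFraction must lie in [0, 1]")
  if (object@depth < 1) msg <- c(msg, "depth must be positive")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated community
#'
#' @slot basisCorrelation Planted latent correlation matrix of log abundances.
#' @slot modules Named integer vector genome -> module (0 = background).
#' @slot rolesByVitamin Named list of named role vectors per vitamin.
#' @slot nearComplete Named list of genome ids planted near-complete.
#' @slot hubId Planted hub genome.
#' @slot dependents Hub-dependent auxotroph genomes.
#' @slot lengths Genome lengths (bp), larger for broader vitamin repertoires.
#' @export
#' @aliases SyntheticTruth-class
setClass("SyntheticTruth",
         representation(basisCorrelation = "matrix", modules = "integer",
                        rolesByVitamin = "list", nearComplete = "list",
                        hubId = "character", dependents = "character",
                        lengths = "numeric"))

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d genomes, %d modules, hub %s with %d dependents\n",
    length(object@modules), length(setdiff(unique(object@modules), 0L)),
    object@hubId, length(object@dependents)))
})
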