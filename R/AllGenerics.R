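#' Genome identifiers
#'
#' Accessor for the genome (node) identifiers carried by vitnet objects.
#'
#' @param x An object with genome identifiers (an [AbundanceTable],
#'   [CorrelationMatrix], [AnnotationSet] or [CooccurrenceNetwork]).
#' @return Character vector of genome identifiers.
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' Sample identifiers
#'
#' @param x An [AbundanceTable] or [SampleMetadata].
#' @return Character vector of sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Relative-abundance matrix
#'
#' @param x An [AbundanceTable].
#' @return Numeric genome-by-sample matrix of fractions in `[0, 1]`.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' Correlation matrix values
#'
#' @param x A [CorrelationMatrix].
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))

#' Permutation p-values
#'
#' @param x A [CorrelationMatrix].
#' @return Symmetric matrix of p-values, or `NULL` when none were computed.
#' @export
setGeneric("pvalues", function(x) standardGeneric("pvalues"))

#' Per-genome KEGG ortholog sets
#'
#' @param x An [AnnotationSet].
#' @return A named [IRanges::CharacterList], one element per genome.
#' @export
setGeneric("koSets", function(x) standardGeneric("koSets"))

#' Genome lengths in base pairs
#'
#' @param x An [AnnotationSet].
#' @return Named numeric vector (bp); `NA` where no length is known.
#' @export
setGeneric("genomeLengths", function(x) standardGeneric("genomeLengths"))

#' Vitamins described by a pathway catalog
#'
#' @param x A [PathwayCatalog].
#' @return Character vector of vitamin names.
#' @export
setGeneric("vitaminNames", function(x) standardGeneric("vitaminNames"))

#' Underlying igraph object of a network
#'
#' @param x A [CooccurrenceNetwork].
#' @return An `igraph` graph with vertex names and edge `weight` attributes.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' Producer/auxotroph role vector
#'
#' @param x A [RoleLabels].
#' @return Named character vector with values `"producer"` / `"auxotroph"`.
#' @export
setGeneric("roles", function(x) standardGeneric("roles"))

#' Number of producer-labeled genomes
#'
#' @param x A [RoleLabels].
#' @return Integer count.
#' @export
setGeneric("nProducers", function(x) standardGeneric("nProducers"))

#' Number of auxotroph-labeled genomes
#'
#' @param x A [RoleLabels].
#' @return Integer count.
#' @export
setGeneric("nAuxotrophs", function(x) standardGeneric("nAuxotrophs"))
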