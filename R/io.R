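#' @include AllClasses.R
NULL

## Canonical tabular dialect: tab-delimited, UTF-8, '#' comment lines ignored.

.readTsv <- function(path, header = TRUE) {
  utils::read.delim(path, header = header, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
}

.fmtNum <- function(x) sprintf("%.17g", x)

#' Read a genome-by-sample abundance table
#'
#' Expects a TSV with a header row of sample ids and genome ids in the first
#' column. Percent input is converted to fractions on load; the stored unit is
#' always a fraction in `[0, 1]`.
#'
#' @param path Path to the TSV file.
#' @param unit `"fraction"` or `"percent"`.
#' @return An [AbundanceTable].
#' @export
readAbundanceTable <- function(path, unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  df <- .readTsv(path)
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("empty abundance table: need at least one genome and one sample")
  ids <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate genome_id '%s'", ids[duplicated(ids)][1L]))
  if (anyDuplicated(samples))
    stop(sprintf("duplicate sample_id '%s'", samples[duplicated(samples)][1L]))
  body <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric abundance at genome '%s', sample '%s'",
                 ids[bad[1L]], samples[bad[2L]]))
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at genome '%s', sample '%s'",
                 ids[bad[1L]], samples[bad[2L]]))
  }
  dimnames(vals) <- list(ids, samples)
  AbundanceTable(vals, unit = unit)
}

#' Write an abundance table as TSV
#'
#' Fractions are serialized at full double precision so that a write/read
#' round trip is an identity.
#'
#' @param tab An [AbundanceTable].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(tab, path) {
  stopifnot(is(tab, "AbundanceTable"))
  v <- abundances(tab)
  out <- cbind(genome_id = rownames(v),
               matrix(.fmtNum(v), nrow(v), ncol(v),
                      dimnames = list(NULL, colnames(v))))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `lifestyle` (biofilm/planktonic) and
#' `scn_level` (high/low); further columns are carried through.
#'
#' @param path Path to the TSV file.
#' @return A [SampleMetadata].
#' @export
readSampleMetadata <- function(path) {
  df <- .readTsv(path)
  if (!"sample_id" %in% colnames(df))
    stop("metadata must have a 'sample_id' column")
  SampleMetadata(df)
}

#' Write sample metadata as TSV
#'
#' @param meta A [SampleMetadata].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSampleMetadata <- function(meta, path) {
  stopifnot(is(meta, "SampleMetadata"))
  df <- as.data.frame(meta)
  df <- cbind(sample_id = rownames(df), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genome annotations (KO sets and genome lengths)
#'
#' `koPath` is a long-format TSV with columns `genome_id` and `ko_id`; repeated
#' (genome, KO) rows are deduplicated, and a row with an empty `ko_id` lists a
#' genome without asserting any annotation. `lengthsPath` is a TSV with columns
#' `genome_id` and `length_bp`. Genomes present in either file are retained; a
#' genome with annotations but no length triggers a warning and is excluded
#' from genome-size analyses only.
#'
#' @param koPath Path to the long-format annotation TSV.
#' @param lengthsPath Optional path to the genome-length TSV.
#' @return An [AnnotationSet].
#' @export
readAnnotations <- function(koPath, lengthsPath = NULL) {
  df <- .readTsv(koPath)
  if (!all(c("genome_id", "ko_id") %in% colnames(df)))
    stop("annotation TSV must have columns 'genome_id' and 'ko_id'")
  nonEmpty <- nzchar(df$ko_id)
  bad <- df$ko_id[nonEmpty][!grepl("^K[0-9]{5}$", df$ko_id[nonEmpty])]
  if (length(bad))
    stop(sprintf("malformed KO id '%s'", bad[1L]))
  ko <- split(df$ko_id[nonEmpty], df$genome_id[nonEmpty])
  listedOnly <- setdiff(unique(df$genome_id), names(ko))
  ko[listedOnly] <- list(character())
  lens <- numeric()
  if (!is.null(lengthsPath)) {
    ldf <- .readTsv(lengthsPath)
    if (!all(c("genome_id", "length_bp") %in% colnames(ldf)))
      stop("length TSV must have columns 'genome_id' and 'length_bp'")
    lens <- as.numeric(ldf$length_bp)
    names(lens) <- ldf$genome_id
    if (anyNA(lens))
      stop("non-numeric genome length")
  }
  ann <- AnnotationSet(ko, lens)
  noLen <- genomeIds(ann)[is.na(genomeLengths(ann)) &
                            lengths(koSets(ann)) > 0]
  if (length(noLen))
    warning(sprintf(
      "%d genome(s) have annotations but no length (excluded from size analyses): %s",
      length(noLen), paste(utils::head(noLen, 5), collapse = ", ")))
  ann
}

#' Write genome annotations as TSV
#'
#' @param ann An [AnnotationSet].
#' @param koPath Output path for the long-format KO table.
#' @param lengthsPath Optional output path for the genome-length table.
#' @return `koPath`, invisibly.
#' @export
writeAnnotations <- function(ann, koPath, lengthsPath = NULL) {
  stopifnot(is(ann, "AnnotationSet"))
  ko <- koSets(ann)
  n <- lengths(ko)
  df <- data.frame(
    genome_id = rep(names(ko), ifelse(n == 0, 1L, n)),
    ko_id = unlist(lapply(as.list(ko), function(k)
      if (length(k)) k else ""), use.names = FALSE))
  utils::write.table(df, koPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lengthsPath)) {
    ln <- genomeLengths(ann)
    ln <- ln[!is.na(ln)]
    utils::write.table(
      data.frame(genome_id = names(ln), length_bp = .fmtNum(ln)),
      lengthsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(koPath)
}

#' Read a vitamin pathway catalog from JSON
#'
#' Schema: `{vitamin: {stages: [{name, kos: [...]}, ...],
#' near_complete_exempt_kos: [...]}}`.
#'
#' @param path Path to the JSON file.
#' @return A [PathwayCatalog].
#' @export
readPathwayCatalog <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  vitamins <- lapply(js, function(v) {
    stages <- lapply(v$stages, function(s) unlist(s$kos))
    names(stages) <- vapply(v$stages, function(s) s$name, "")
    list(stages = stages,
         exempt = as.character(unlist(v$near_complete_exempt_kos)))
  })
  PathwayCatalog(vitamins)
}

#' Write a vitamin pathway catalog as JSON
#'
#' @param cat A [PathwayCatalog].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePathwayCatalog <- function(cat, path) {
  stopifnot(is(cat, "PathwayCatalog"))
  js <- lapply(cat@vitamins, function(v) {
    list(stages = unname(Map(function(nm, kos)
      list(name = nm, kos = as.list(kos)),
      names(v$stages), v$stages)),
      near_complete_exempt_kos = as.list(v$exempt))
  })
  jsonlite::write_json(js, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The shipped six-vitamin pathway catalog
#'
#' Default catalog for thiamine, biotin, tetrahydrofolate, riboflavin, NAD and
#' pantothenate. The thiamine definition follows the four-stage rule (thiazole
#' production, pyrimidine synthesis, moiety linking, kinases) with K03147
#' (thiC) as the single exempt KO whose sole absence leaves the pathway
#' near-complete. KO lists are editable config data, not code.
#'
#' @return A [PathwayCatalog].
#' @export
defaultPathwayCatalog <- function() {
  readPathwayCatalog(system.file("extdata", "vitamin_pathways.json",
                                 package = "vitnet", mustWork = TRUE))
}

#' Read a square correlation matrix (and optional p-values) from TSV
#'
#' @param path Path to the correlation TSV (square, header ids, first column
#'   ids).
#' @param pvaluesPath Optional path to a matching p-value TSV.
#' @return A [CorrelationMatrix].
#' @export
readCorrelationMatrix <- function(path, pvaluesPath = NULL) {
  readSquare <- function(p) {
    df <- .readTsv(p)
    ids <- df[[1L]]
    m <- matrix(as.numeric(as.matrix(df[, -1L, drop = FALSE])),
                nrow(df), ncol(df) - 1L,
                dimnames = list(ids, colnames(df)[-1L]))
    if (!identical(rownames(m), colnames(m)))
      stop("correlation matrix must be square with identical row/column ids")
    m
  }
  r <- readSquare(path)
  p <- if (is.null(pvaluesPath)) NULL else readSquare(pvaluesPath)
  ## guard against last-digit asymmetry from serialization
  r <- (r + t(r)) / 2
  diag(r) <- 1
  if (!is.null(p)) p <- (p + t(p)) / 2
  CorrelationMatrix(r, p)
}

#' Write a correlation matrix (and optional p-values) as TSV
#'
#' P-values, when present, go to a sibling file (default: the correlation
#' path with extension `.pvals.tsv`).
#'
#' @param x A [CorrelationMatrix].
#' @param path Output path for the correlation TSV.
#' @param pvaluesPath Output path for the p-value TSV; defaults to a sibling
#'   of `path`.
#' @return `path`, invisibly.
#' @export
writeCorrelationMatrix <- function(x, path, pvaluesPath = NULL) {
  stopifnot(is(x, "CorrelationMatrix"))
  writeSquare <- function(m, p) {
    out <- cbind(genome_id = rownames(m),
                 matrix(.fmtNum(m), nrow(m), ncol(m),
                        dimnames = list(NULL, colnames(m))))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeSquare(correlations(x), path)
  if (!is.null(pvalues(x))) {
    if (is.null(pvaluesPath))
      pvaluesPath <- if (grepl("\\.tsv$", path))
        sub("\\.tsv$", ".pvals.tsv", path) else paste0(path, ".pvals.tsv")
    writeSquare(pvalues(x), pvaluesPath)
  }
  invisible(path)
}

#' Write a co-occurrence network to disk
#'
#' GraphML (the import format of interactive viewers such as Cytoscape) or a
#' three-column `source<TAB>target<TAB>weight` edge list with each undirected
#' edge written once.
#'
#' @param net A [CooccurrenceNetwork].
#' @param path Output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("graphml", "edge_tsv")) {
  stopifnot(is(net, "CooccurrenceNetwork"))
  format <- match.arg(format)
  g <- networkGraph(net)
  if (format == "graphml") {
    g <- igraph::set_graph_attr(g, "threshold", net@threshold)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(g, what = "edges")
    out <- data.frame(source = ed$from, target = ed$to,
                      weight = .fmtNum(ed$weight))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a co-occurrence network from disk
#'
#' @param path Path written by [writeNetwork()].
#' @param format `"graphml"` or `"edge_tsv"`.
#' @param threshold Construction threshold to record; for GraphML the stored
#'   graph attribute is used when available.
#' @return A [CooccurrenceNetwork].
#' @export
readNetwork <- function(path, format = c("graphml", "edge_tsv"),
                        threshold = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "each")
    thr <- igraph::graph_attr(g, "threshold")
    if (is.null(threshold))
      threshold <- if (is.null(thr)) {
        if (igraph::ecount(g)) min(igraph::E(g)$weight) else 0.35
      } else thr
  } else {
    df <- .readTsv(path)
    if (!all(c("source", "target", "weight") %in% colnames(df)))
      stop("edge TSV must have columns source, target, weight")
    g <- igraph::graph_from_data_frame(
      data.frame(from = df$source, to = df$target,
                 weight = as.numeric(df$weight)),
      directed = FALSE)
    if (is.null(threshold))
      threshold <- if (igraph::ecount(g)) min(igraph::E(g)$weight) else 0.35
  }
  CooccurrenceNetwork(g, threshold = threshold)
}

#' Convert raw per-sample counts to relative abundances
#'
#' Each sample (column) is divided by its total, so the result is invariant
#' to per-sample sequencing depth.
#'
#' @param counts Non-negative numeric matrix (genomes x samples) with
#'   dimnames.
#' @return An [AbundanceTable].
#' @export
abundanceFromCounts <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- colSums(counts)
  if (any(tot == 0)) stop("every sample must have a positive total count")
  AbundanceTable(sweep(counts, 2L, tot, "/"))
}
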