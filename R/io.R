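#' The 21-gene 5mC regulator catalog
#'
#' Writers (DNA methyltransferases), erasers (TET dioxygenases plus TDG), and
#' methyl-CpG readers. Eleven reader genes are named in the source literature
#' while the class is described as holding fourteen; the remaining three slots
#' ship as explicit placeholders (`READER12`--`READER14`) that callers should
#' override with their own curation rather than have the package guess.
#'
#' @param readers Optional character vector of 14 reader gene symbols
#'   replacing the default reader list (placeholders included).
#' @return Data frame with columns `gene` and `role`
#'   (writer/eraser/reader), 21 rows.
#' @export
regulatorCatalog <- function(readers = NULL) {
  writers <- c("DNMT3A", "DNMT3B", "DNMT1")
  erasers <- c("TET1", "TET2", "TET3", "TDG")
  if (is.null(readers)) {
    readers <- c("MBD1", "MBD2", "MBD3", "MBD4", "MECP2", "NEIL1", "NTHL1",
                 "SMUG1", "UHRF1", "UHRF2", "UNG",
                 "READER12", "READER13", "READER14")
  }
  if (length(readers) != 14L)
    stopf("the catalog requires exactly 14 reader genes (got %d)", length(readers))
  out <- data.frame(
    gene = c(writers, erasers, readers),
    role = rep(c("writer", "eraser", "reader"), c(3L, 4L, 14L)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene)) stopf("regulator catalog genes must be unique")
  out
}

#' Default run configuration
#'
#' All tunables of the pipeline with their defaults: consensus-clustering
#' resampling parameters (80% item and feature resampling, 1000 replicates,
#' maximum k of 6), DEG thresholds (adjusted p < 0.001, |log2FC| > 1.5),
#' the univariate-Cox prognostic filter alpha (0.05), the ssGSEA exponent
#' (0.25), the cutpoint minimum group proportion (0.1), DMP thresholds
#' (adjusted p < 0.01, beta 0.2/0.5), and the master seed.
#'
#' @return Named list of configuration values.
#' @export
defaultConfig <- function() {
  list(
    pItem = 0.8,
    pFeature = 0.8,
    maxK = 6L,
    reps = 1000L,
    degAdjPMax = 0.001,
    degMinAbsLog2FC = 1.5,
    coxAlpha = 0.05,
    ssgseaAlpha = 0.25,
    ssgseaNormalize = TRUE,
    cutpointMinprop = 0.1,
    dmpAdjPMax = 0.01,
    betaLow = 0.2,
    betaHigh = 0.5,
    seed = 1L
  )
}

#' Read or write a run configuration (flat YAML)
#'
#' `readConfig()` merges the keys found in a flat YAML file over
#' [defaultConfig()]; unknown keys are rejected. `writeConfig()` serialises a
#' configuration so every run can store the resolved parameters and seed next
#' to its outputs.
#'
#' @param path File path.
#' @param config Named configuration list.
#' @return `readConfig()` returns the merged configuration list.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- defaultConfig()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown))
    stopf("unknown configuration keys: %s", paste(unknown, collapse = ", "))
  cfg[names(vals)] <- vals
  cfg$maxK <- as.integer(cfg$maxK)
  cfg$reps <- as.integer(cfg$reps)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.read_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "")
}

#' Read a gene-by-sample expression matrix
#'
#' Tab-separated with a header row of sample ids and gene ids in the first
#' column. Duplicate gene rows are collapsed by the per-sample maximum (the
#' usual TPM convention) with a logged warning; missing values and, on the
#' linear scale, negative values are rejected naming the first offending
#' cell.
#'
#' @param path TSV path.
#' @param scale Either `"linear_tpm"` or `"log2_tpm_plus1"`.
#' @return Numeric matrix with a `scale` attribute.
#' @export
readExpression <- function(path, scale = c("linear_tpm", "log2_tpm_plus1")) {
  scale <- match.arg(scale)
  df <- .read_table(path)
  genes <- as.character(df[[1L]])
  ids <- names(df)[-1L]
  if (anyDuplicated(ids))
    stopf("duplicate sample ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  colnames(mat) <- ids
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stopf("missing expression value for gene '%s', sample '%s'",
          genes[idx[1L]], colnames(mat)[idx[2L]])
  }
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    mc5Log("collapsing ", length(dups),
           " duplicated gene row(s) by per-sample maximum: ",
           paste(utils::head(dups, 5L), collapse = ", "))
    u <- unique(genes)
    mat <- do.call(rbind, lapply(u, function(g) {
      apply(mat[genes == g, , drop = FALSE], 2L, max)
    }))
    rownames(mat) <- u
    warning(sprintf("collapsed %d duplicated gene row(s) by per-sample maximum",
                    length(dups)), call. = FALSE)
  } else {
    rownames(mat) <- genes
  }
  if (scale == "linear_tpm" && any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stopf("negative TPM for gene '%s', sample '%s'",
          rownames(mat)[idx[1L]], colnames(mat)[idx[2L]])
  }
  attr(mat, "scale") <- scale
  mat
}

#' @rdname readExpression
#' @param expr Matrix to write.
#' @export
writeExpression <- function(expr, path) {
  assertMatrix(expr, "expression matrix")
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Requires `sample_id`, `os_time` (days, strictly positive), `os_event`
#' (0/1); `stage`, `grade`, `lvi`, `age` and `purity` (CPE fraction in
#' \[0,1\]) are optional.
#'
#' @param path TSV path.
#' @return Data frame keyed by unique `sample_id`.
#' @export
readClinical <- function(path) {
  df <- .read_table(path)
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("clinical table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stopf("duplicate clinical sample ids")
  validateClinical(df)
  df
}

validateClinical <- function(df) {
  ok <- !is.na(df$os_time)
  if (any(df$os_time[ok] <= 0))
    stopf("os_time must be > 0 (first offender: sample '%s')",
          df$sample_id[ok][which(df$os_time[ok] <= 0)[1L]])
  ev <- df$os_event[!is.na(df$os_event)]
  if (!all(ev %in% c(0, 1))) stopf("os_event must be 0 or 1")
  if ("purity" %in% names(df)) {
    pu <- df$purity[!is.na(df$purity)]
    if (any(pu < 0 | pu > 1)) stopf("purity must lie in [0,1]")
  }
  invisible(TRUE)
}

#' @rdname readClinical
#' @param clinical Data frame to write.
#' @export
writeClinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene tokens.
#' Tokens may carry a direction suffix `|+1` or `|-1` (default +1), the
#' signed dialect used by the cancer-immunity-cycle step sets. Duplicate
#' genes within a line are dropped (first occurrence wins).
#'
#' @param path GMT path.
#' @return Named list; each element has `genes` (character) and `weights`
#'   (+1/-1 per gene).
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    name <- trimws(parts[1L])
    if (!nzchar(name)) stopf("blank gene-set name on line %d", i)
    tokens <- parts[-(1:2)]
    tokens <- tokens[nzchar(tokens)]
    if (!length(tokens)) stopf("gene set '%s' on line %d has no genes", name, i)
    if (name %in% names(out)) stopf("duplicated gene-set name '%s' (line %d)", name, i)
    genes <- sub("\\|[+-]?1$", "", tokens)
    weights <- ifelse(grepl("\\|-1$", tokens), -1, 1)
    keep <- !duplicated(genes)
    out[[name]] <- list(genes = genes[keep],
                        weights = stats::setNames(weights[keep], genes[keep]))
  }
  out
}

#' @rdname readGeneSets
#' @param sets Gene-set collection to write.
#' @export
writeGeneSets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    tok <- ifelse(s$weights[s$genes] < 0, paste0(s$genes, "|-1"), s$genes)
    paste(c(nm, "na", tok), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read 450k-style methylation data
#'
#' Beta values (probe-by-sample TSV, strictly inside \[0,1\]) plus a probe
#' annotation TSV with columns `probe`, `gene` (semicolon-joined symbols) and
#' `region` (semicolon-joined region groups, aligned with the genes). Probes
#' present in the beta matrix but absent from the annotation are retained
#' with empty annotation.
#'
#' @param betaPath,annotationPath TSV paths.
#' @return List with `beta` (matrix) and `annotation` (long data frame:
#'   probe, gene, region).
#' @export
readMethylation <- function(betaPath, annotationPath) {
  df <- .read_table(betaPath)
  probes <- as.character(df[[1L]])
  if (anyDuplicated(probes))
    stopf("duplicated probe id '%s'", probes[duplicated(probes)][1L])
  beta <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- probes
  if (anyNA(beta)) {
    idx <- which(is.na(beta), arr.ind = TRUE)[1L, ]
    stopf("missing beta value for probe '%s', sample '%s'",
          probes[idx[1L]], colnames(beta)[idx[2L]])
  }
  if (any(beta < 0 | beta > 1)) {
    idx <- which(beta < 0 | beta > 1, arr.ind = TRUE)[1L, ]
    stopf("beta value outside [0,1] for probe '%s', sample '%s'",
          probes[idx[1L]], colnames(beta)[idx[2L]])
  }
  anno <- parseProbeAnnotation(annotationPath)
  list(beta = beta, annotation = anno)
}

parseProbeAnnotation <- function(path) {
  df <- .read_table(path)
  need <- c("probe", "gene", "region")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("probe annotation lacks column(s): %s", paste(miss, collapse = ", "))
  regions <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")
  rows <- lapply(seq_len(nrow(df)), function(i) {
    g <- strsplit(df$gene[i], ";", fixed = TRUE)[[1L]]
    r <- strsplit(df$region[i], ";", fixed = TRUE)[[1L]]
    if (length(g) != length(r))
      stopf("probe '%s': %d gene(s) but %d region group(s)", df$probe[i], length(g), length(r))
    data.frame(probe = df$probe[i], gene = g, region = r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(probe = character(), gene = character(),
                                      region = character(), stringsAsFactors = FALSE)
  bad <- setdiff(unique(out$region), regions)
  if (length(bad))
    stopf("unknown probe region group(s): %s", paste(bad, collapse = ", "))
  out
}

#' @rdname readMethylation
#' @param beta Beta matrix to write.
#' @param annotation Long annotation data frame (probe, gene, region).
#' @export
writeMethylation <- function(beta, annotation, betaPath, annotationPath) {
  assertMatrix(beta, "beta matrix")
  df <- data.frame(probe = rownames(beta), beta, check.names = FALSE)
  utils::write.table(df, betaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  agg <- lapply(split(annotation, annotation$probe), function(a) {
    data.frame(probe = a$probe[1L],
               gene = paste(a$gene, collapse = ";"),
               region = paste(a$region, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  anno <- do.call(rbind, agg)
  utils::write.table(anno, annotationPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(betaPath)
}

#' Read a binary mutation table
#'
#' Sample-by-gene matrix with entries 0/1 (1 = nonsilent mutation present).
#'
#' @param path TSV path (first column sample ids).
#' @return Binary numeric matrix.
#' @export
readMutations <- function(path) {
  df <- .read_table(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stopf("duplicate mutation sample ids")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (anyNA(mat) || !all(mat %in% c(0, 1)))
    stopf("mutation table entries must all be 0 or 1")
  mat
}

#' @rdname readMutations
#' @param mutations Matrix to write.
#' @export
writeMutations <- function(mutations, path) {
  df <- data.frame(sample_id = rownames(mutations), mutations, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read T-cell-inflamed score (TIS) coefficients
#'
#' Two-column TSV (gene, coefficient) carrying the 18 published
#' IFN-gamma-responsive gene weights. The coefficients are user-supplied
#' input: they live in the source study's supplementary material and are not
#' invented by this package.
#'
#' @param path TSV path.
#' @return Named numeric vector of length 18.
#' @export
readTisWeights <- function(path) {
  df <- .read_table(path)
  if (ncol(df) < 2L) stopf("TIS weight file needs columns gene, coefficient")
  w <- stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
  if (length(w) != 18L)
    stopf("the TIS requires exactly 18 gene coefficients (got %d)", length(w))
  if (anyDuplicated(names(w))) stopf("duplicated TIS gene symbols")
  if (any(!is.finite(w))) stopf("TIS coefficients must be finite")
  w
}
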