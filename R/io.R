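## Plain-text persistence of a bil_dataset: tab-delimited tables plus a JSON
## ground-truth file. Numbers are written with 17 significant digits so that
## read(write(x)) round-trips doubles exactly.

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}

#' Write a synthetic BIL dataset to a directory
#'
#' Emits `map.tsv` (marker, chromosome, position_cm), `genotypes.tsv`
#' (line_id plus one column per marker, codes OU/AR/HET/NA),
#' `expression.tsv` (gene_id plus one column per sample, FPKM),
#' `trait.tsv` (line_id, replicate, value_mg), `samples.tsv` and
#' `truth.json`. [read_dataset()] restores the dataset exactly.
#'
#' @param dataset a `bil_dataset` from [simulate_bil_dataset()].
#' @param directory output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, directory) {
  if (!inherits(dataset, "bil_dataset")) stop("`dataset` must be a bil_dataset", call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(as.data.frame(dataset$map), file.path(directory, "map.tsv"))

  gt <- data.frame(line_id = rownames(dataset$genotypes),
                   dataset$genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(gt, file.path(directory, "genotypes.tsv"))

  ex <- data.frame(gene_id = rownames(dataset$expression),
                   dataset$expression, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(ex, file.path(directory, "expression.tsv"))

  .write_tsv(dataset$trait$replicates, file.path(directory, "trait.tsv"))
  .write_tsv(dataset$samples, file.path(directory, "samples.tsv"))
  tr <- unclass(dataset$truth)
  # named atomic vectors must become lists to keep their names in JSON
  if (!is.null(tr$parent_means_mg)) tr$parent_means_mg <- as.list(tr$parent_means_mg)
  jsonlite::write_json(tr, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(directory)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

.truth_from_json <- function(path) {
  tr <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (nm in c("qtl", "causal_genes", "eqtl")) {
    if (!is.null(tr[[nm]])) tr[[nm]] <- as.data.frame(tr[[nm]])
  }
  if (!is.null(tr$parent_means_mg)) tr$parent_means_mg <- unlist(tr$parent_means_mg)
  if (!is.null(tr$qpcr)) tr$qpcr <- lapply(tr$qpcr, unlist)
  class(tr) <- "synthetic_truth"
  tr
}

#' Read a BIL dataset written by [write_dataset()]
#'
#' Validates while parsing: genotype codes must be OU/AR/HET/NA (the
#' offending file, line and symbol are named on failure) and the expression
#' matrix must be nonempty with nonnegative values.
#'
#' @param directory directory containing the dataset files.
#' @return a `bil_dataset`.
#' @export
read_dataset <- function(directory) {
  map <- .read_tsv(file.path(directory, "map.tsv"))
  class(map) <- c("genetic_map", "data.frame")
  validate_genetic_map(map)

  gt_df <- .read_tsv(file.path(directory, "genotypes.tsv"))
  geno <- as.matrix(gt_df[, -1, drop = FALSE])
  rownames(geno) <- gt_df$line_id
  bad <- which(!(geno %in% c("OU", "AR", "HET") | is.na(geno)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("parse error in ", file.path(directory, "genotypes.tsv"), " line ",
         bad[1, 1] + 1L, ": illegal genotype code '",
         geno[bad[1, 1], bad[1, 2]], "'", call. = FALSE)
  }
  if (!setequal(colnames(geno), map$marker)) {
    stop("genotypes.tsv markers do not match map.tsv", call. = FALSE)
  }
  geno <- geno[, map$marker, drop = FALSE]

  ex_df <- .read_tsv(file.path(directory, "expression.tsv"))
  if (nrow(ex_df) == 0 || ncol(ex_df) < 2) {
    stop("empty expression matrix in ", file.path(directory, "expression.tsv"),
         call. = FALSE)
  }
  expr <- as.matrix(ex_df[, -1, drop = FALSE])
  if (!is.numeric(expr)) stop("non-numeric expression values in expression.tsv", call. = FALSE)
  if (any(expr < 0)) stop("negative FPKM values in expression.tsv", call. = FALSE)
  rownames(expr) <- ex_df$gene_id

  reps <- .read_tsv(file.path(directory, "trait.tsv"))
  if (!all(c("line_id", "replicate", "value_mg") %in% names(reps))) {
    stop("trait.tsv must have columns line_id, replicate, value_mg", call. = FALSE)
  }
  line_order <- unique(reps$line_id)
  means <- tapply(reps$value_mg, reps$line_id, mean)[line_order]
  trait <- structure(
    list(means = setNames(as.numeric(means), line_order), replicates = reps,
         n_replicates = max(reps$replicate)),
    class = "trait_vector"
  )

  samples <- .read_tsv(file.path(directory, "samples.tsv"))
  truth <- .truth_from_json(file.path(directory, "truth.json"))

  structure(list(map = map, genotypes = geno, trait = trait,
                 expression = expr, samples = samples, truth = truth),
            class = "bil_dataset")
}
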