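# Readers for phenotype/covariate tables and genotype dosages, plus the
# end-to-end association runner behind the command-line front end.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a phenotype/covariate table
#'
#' Delimited text (comma or tab, auto-detected) with a header and a
#' sample-ID column. Rows with a missing trait or covariate are dropped
#' (complete-case), character/factor covariates are one-hot encoded with the
#' first level as reference, and an intercept column is prepended.
#'
#' @param path File path.
#' @param trait_column Name of the trait column.
#' @param covariate_columns Character vector of covariate column names (may
#'   be empty for an intercept-only design).
#' @param id_column Name of the sample-ID column (default: first column).
#' @return List of class `phenotype_data`: `ids`, `trait`, `covariates`
#'   (design matrix with intercept), `n_dropped`.
#' @export
read_phenotypes <- function(path, trait_column, covariate_columns = character(0),
                            id_column = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(id_column)) id_column <- names(tab)[1]
  missing_cols <- setdiff(c(id_column, trait_column, covariate_columns),
                          names(tab))
  if (length(missing_cols))
    stop("columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  ids <- as.character(tab[[id_column]])
  if (anyDuplicated(ids))
    stop("duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  y <- tab[[trait_column]]
  if (!is.numeric(y)) stop("trait column '", trait_column, "' is not numeric")
  if (all(is.na(y))) stop("trait column '", trait_column, "' is all missing")
  keep <- stats::complete.cases(tab[, c(trait_column, covariate_columns),
                                    drop = FALSE])
  tab <- tab[keep, , drop = FALSE]
  if (length(covariate_columns)) {
    fml <- stats::reformulate(sprintf("`%s`", covariate_columns))
    X <- stats::model.matrix(fml, data = tab)
  } else {
    X <- matrix(1, nrow(tab), 1, dimnames = list(NULL, "(Intercept)"))
  }
  structure(list(ids = as.character(tab[[id_column]]),
                 trait = as.numeric(tab[[trait_column]]),
                 covariates = X, n_dropped = sum(!keep)),
            class = "phenotype_data")
}

is_vcf <- function(path) {
  grepl("\\.vcf$", path, ignore.case = TRUE) ||
    startsWith(readLines(path, n = 1L), "##fileformat=VCF")
}

vcf_to_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF genotypes requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixed <- vcfR::getFIX(v)
  if (is.null(dim(fixed))) fixed <- t(as.matrix(fixed))  # single record
  multi <- grepl(",", fixed[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
    v <- v[!multi, ]
    fixed <- fixed[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # additive ALT dosage; missing GT -> NA
  count_alt <- function(x) {
    ifelse(is.na(x) | grepl("\\.", x), NA_real_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), 0))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1,
                                       dimnames = list(NULL, names(dos)))
  ids <- fixed[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fixed[blank, "CHROM"], ":", fixed[blank, "POS"])
  out <- t(dos)
  colnames(out) <- ids
  out
}

#' Read a genotype dosage matrix
#'
#' Either a delimited table (rows = samples with an ID column, columns =
#' variants, dosages in `[0, 2]`, `NA` allowed) or a VCF whose GT fields are
#' converted to additive ALT-allele dosages (multi-allelic sites skipped with
#' a warning; missing GT becomes missing dosage).
#'
#' @param path File path.
#' @return Numeric matrix (samples x variants) with sample IDs as row names;
#'   attributes `missingness` (per-variant missing fraction) and
#'   `zero_variance` (logical per variant).
#' @export
read_genotypes <- function(path) {
  if (is_vcf(path)) {
    G <- vcf_to_dosage(path)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                             stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(tab[[1]])
    G <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(G) <- "double"
    rownames(G) <- ids
  }
  if (any(G < 0 | G > 2, na.rm = TRUE))
    stop("dosages outside [0, 2] in ", path)
  miss <- colMeans(is.na(G))
  zv <- apply(G, 2, function(g) stats::var(g, na.rm = TRUE)) %in% c(0, NA)
  attr(G, "missingness") <- miss
  attr(G, "zero_variance") <- zv
  G
}

#' Run a file-to-file association analysis
#'
#' Reads phenotypes and genotypes, aligns samples by ID (row order in either
#' file is irrelevant), runs the requested method(s) on each variant with
#' per-variant complete-case handling, and writes a tab-separated results
#' file with one row per (variant, method). A comment header records the
#' seed, package version and a configuration hash; p-values are printed in
#' scientific notation with 6 significant digits.
#'
#' @param phenotype_file,genotype_file Input paths (see [read_phenotypes()],
#'   [read_genotypes()]).
#' @param trait_column,covariate_columns,id_column Phenotype-table columns.
#' @param method Method key or `"all"`.
#' @param output_path Output file (`NULL` returns the table only).
#' @param seed Seed applied before the analysis (only stochastic methods,
#'   e.g. the median-regression bootstrap, consume it).
#' @param ... Method options passed to [int_assoc()].
#' @return The results data frame, invisibly.
#' @export
run_association <- function(phenotype_file, genotype_file, trait_column,
                            covariate_columns = character(0),
                            id_column = NULL, method = "all",
                            output_path = NULL, seed = 1L, ...) {
  ph <- read_phenotypes(phenotype_file, trait_column, covariate_columns,
                        id_column)
  G <- read_genotypes(genotype_file)
  common <- intersect(ph$ids, rownames(G))
  if (length(common) == 0) stop("no sample IDs shared between files")
  common <- sort(common)
  idx <- match(common, ph$ids)
  df <- data.frame(.y = ph$trait[idx], check.names = FALSE)
  X <- ph$covariates[idx, , drop = FALSE]
  Gm <- G[match(common, rownames(G)), , drop = FALSE]

  set.seed(seed)
  covars <- setdiff(colnames(X), "(Intercept)")
  df <- cbind(df, as.data.frame(X[, covars, drop = FALSE]))
  fml <- if (length(covars))
    stats::reformulate(sprintf("`%s`", covars), response = ".y")
  else stats::as.formula(".y ~ 1")
  fit <- int_assoc(fml, df, genotype = Gm, method = method, ...)
  res <- fit$results
  res$p_value <- format(res$p_value, scientific = TRUE, digits = 6)

  if (!is.null(output_path)) {
    cfg <- paste(trait_column, paste(covariate_columns, collapse = "+"),
                 method, seed, sep = "|")
    hash <- sum(utf8ToInt(cfg) * seq_along(utf8ToInt(cfg))) %% 1000000L
    con <- file(output_path, "w")
    writeLines(c(
      paste0("# fsint v", as.character(utils::packageVersion("fsint"))),
      paste0("# seed=", seed, " config_hash=", hash),
      paste0("# samples_used=", length(common))), con)
    utils::write.table(res, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(res)
}
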