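# Shared fixtures, built in code.

# the four-point dataset whose OLS algebra is done by hand in the tests
toy4 <- function() {
  list(y = c(1, 2, 3, 4),
       X = matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)")),
       g = c(0, 0, 1, 1))
}

# dataset with covariates for compositional oracles
make_cov_data <- function(n = 300, seed = 1, errors = c("normal", "chisq",
                                                        "mixture"),
                          beta = 0, maf = 0.2) {
  errors <- match.arg(errors)
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.5)
  g <- rbinom(n, 2, maf)
  eps <- switch(errors,
                normal = rnorm(n),
                chisq = rchisq(n, 2),
                mixture = ifelse(runif(n) < 0.05, rnorm(n, 0, 5),
                                 rnorm(n, 0, 0.05)))
  y <- 0.5 * x1 + 0.5 * x2 + beta * g + eps
  sample_data(y, g, cbind("(Intercept)" = 1, x1 = x1, x2 = x2))
}

write_pheno_fixture <- function(path = tempfile(fileext = ".csv")) {
  df <- data.frame(sample_id = paste0("S", 1:5),
                   bmi = c(21.5, 24.2, 30.1, 27.8, 23.3),
                   age = c(34, 51, NA, 42, 60),
                   group = c("A", "B", "A", "B", "A"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_vcf_fixture <- function(path = tempfile(fileext = ".vcf"),
                              with_multiallelic = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=1000000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    paste(c("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
            "0/1", "./.", "0/0"), collapse = "\t"))
  if (with_multiallelic)
    lines <- c(lines,
               paste(c("1", "300", "rs3", "G", "A,C", ".", "PASS", ".", "GT",
                       "0/1", "0/2", "0/0"), collapse = "\t"))
  writeLines(lines, path)
  path
}

# dosage table matching the biallelic records of the VCF fixture
write_dosage_fixture <- function(path = tempfile(fileext = ".csv"),
                                 shuffle = FALSE) {
  df <- data.frame(sample_id = c("S1", "S2", "S3"),
                   rs1 = c(0, 1, 2), rs2 = c(1, NA, 0))
  if (shuffle) df <- df[c(3, 1, 2), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
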