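#' Genotype panel container
#'
#' An N x M dosage matrix plus sample ids, SNP ids and an optional binary
#' phenotype. Dosages count copies of the panel minor allele: orientation
#' is recomputed on load, so `mean(dosage)/2 <= 0.5` for every SNP; at an
#' exact 50/50 tie the incoming orientation is kept (for allele-coded input
#' the alphabetically first allele serves as the reference).
#'
#' @param dosages N x M matrix in \{0, 1, 2, NA\}.
#' @param phenotype length-N vector in \{0, 1, NA\}, or `NULL`.
#' @param snp_ids,sample_ids identifiers; defaults generated when missing.
#' @return A `genotype_panel`.
#' @export
genotype_panel <- function(dosages, phenotype = NULL, snp_ids = NULL,
                           sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(snp_ids)) snp_ids <- colnames(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (is.null(sample_ids)) sample_ids <- rownames(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("id", seq_len(nrow(dosages)))
  if (is.null(phenotype)) phenotype <- rep(NA_integer_, nrow(dosages))
  stopifnot(length(snp_ids) == ncol(dosages),
            length(sample_ids) == nrow(dosages),
            length(phenotype) == nrow(dosages))
  if (!all(is.na(phenotype) | phenotype %in% c(0, 1)))
    stop("phenotype must be coded 0/1, NA for missing")
  # minor-allele orientation
  fr <- colMeans(dosages, na.rm = TRUE) / 2
  flip <- !is.na(fr) & fr > 0.5
  dosages[, flip] <- 2L - dosages[, flip]
  dimnames(dosages) <- list(sample_ids, snp_ids)
  structure(list(dosages = dosages, snp_ids = snp_ids,
                 sample_ids = sample_ids,
                 phenotype = as.integer(phenotype)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype panel: %d samples x %d SNPs; phenotype: %d cases, %d controls, %d missing\n",
              nrow(x$dosages), ncol(x$dosages),
              sum(x$phenotype == 1L, na.rm = TRUE),
              sum(x$phenotype == 0L, na.rm = TRUE),
              sum(is.na(x$phenotype))))
  invisible(x)
}

.io_error <- function(path, line, field, what) {
  stop(sprintf("%s: line %d, field %s: %s", path, line, field, what))
}

#' Read a genotype panel from text formats
#'
#' Supported formats:
#' * `plink_ped_map`: `path` is the file prefix; `<path>.ped` and
#'   `<path>.map` are read. Allele pairs are recoded to minor-allele
#'   dosages (`0 0` = missing); phenotype 1/2 maps to control/case, 0 and
#'   -9 to missing.
#' * `plink_raw`: additive-coding export (header `FID IID PAT MAT SEX
#'   PHENOTYPE <snp>_<allele> ...`), `NA` missing.
#' * `delimited_dosage`: tab-delimited with header
#'   `sample_id phenotype <snp> ...`, dosage entries 0/1/2/NA.
#'
#' @param path file path (prefix for `plink_ped_map`).
#' @param format one of the above.
#' @return A `genotype_panel`.
#' @export
read_panel <- function(path, format = c("delimited_dosage", "plink_ped_map",
                                        "plink_raw")) {
  format <- match.arg(format)
  switch(format,
         plink_ped_map = .read_ped_map(path),
         plink_raw = .read_raw(path),
         delimited_dosage = .read_dosage(path))
}

.map_phenotype <- function(ph) {
  ph <- suppressWarnings(as.numeric(ph))
  out <- rep(NA_integer_, length(ph))
  out[!is.na(ph) & ph == 1] <- 0L
  out[!is.na(ph) & ph == 2] <- 1L
  out
}

.read_ped_map <- function(prefix) {
  ped_path <- paste0(prefix, ".ped"); map_path <- paste0(prefix, ".map")
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE)
  snp_ids <- as.character(map[[2L]])
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  M <- length(snp_ids)
  n <- length(lines)
  alle <- matrix(NA_character_, n, 2L * M)
  ids <- character(n); ph <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) != 6L + 2L * M)
      .io_error(ped_path, i, length(f),
                sprintf("expected %d fields, found %d", 6L + 2L * M, length(f)))
    ids[i] <- f[2L]; ph[i] <- f[6L]
    alle[i, ] <- f[-(1:6)]
  }
  dos <- matrix(NA_integer_, n, M)
  for (m in seq_len(M)) {
    a1 <- alle[, 2L * m - 1L]; a2 <- alle[, 2L * m]
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    if (length(obs) == 0L) next
    tab <- table(obs)
    lev <- names(tab)
    # minor = least frequent; on a tie the alphabetically first allele is
    # taken as the reference and the other one is counted
    minor <- if (length(lev) == 1L) lev else {
      cand <- lev[tab == min(tab)]
      if (length(cand) > 1L) sort(cand)[2L] else cand
    }
    dos[, m] <- (a1 == minor) + (a2 == minor)
    dos[miss, m] <- NA_integer_
  }
  genotype_panel(dos, phenotype = .map_phenotype(ph),
                 snp_ids = snp_ids, sample_ids = ids)
}

.read_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", "-9"))
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(need %in% names(df)))
    stop(path, ": missing PLINK .raw header columns")
  snp_cols <- setdiff(names(df), need)
  dos <- as.matrix(df[, snp_cols, drop = FALSE])
  if (!all(is.na(dos) | dos %in% c(0, 1, 2)))
    stop(path, ": dosage entries must be 0/1/2/NA")
  snp_ids <- sub("_[ACGT0-9]+$", "", snp_cols)
  genotype_panel(dos, phenotype = .map_phenotype(df$PHENOTYPE),
                 snp_ids = snp_ids, sample_ids = as.character(df$IID))
}

.read_dosage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "phenotype") %in% names(df)))
    stop(path, ": expected 'sample_id' and 'phenotype' columns")
  snp_cols <- setdiff(names(df), c("sample_id", "phenotype"))
  dos <- as.matrix(df[, snp_cols, drop = FALSE])
  if (!all(is.na(dos) | dos %in% c(0, 1, 2)))
    stop(path, ": dosage entries must be 0/1/2/NA")
  genotype_panel(dos, phenotype = df$phenotype,
                 snp_ids = snp_cols, sample_ids = as.character(df$sample_id))
}

#' Write a genotype panel as a delimited dosage table
#'
#' Tab-delimited text with columns `sample_id`, `phenotype` and one dosage
#' column per SNP; reads back identically via
#' `read_panel(format = "delimited_dosage")`.
#'
#' @param panel a `genotype_panel`.
#' @param path output file.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- data.frame(sample_id = panel$sample_ids,
                   phenotype = panel$phenotype,
                   panel$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype panel as PLINK .ped/.map text
#'
#' Dosage d is written as d copies of allele `G` (the minor allele) and
#' 2 - d copies of `A`; missing dosages become `0 0`. Phenotype is written
#' in PLINK 1/2 coding (0 = missing).
#'
#' @param panel a `genotype_panel`.
#' @param prefix output prefix (`<prefix>.ped`, `<prefix>.map`).
#' @export
write_ped <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  M <- ncol(panel$dosages)
  map <- data.frame(chr = 1L, snp = panel$snp_ids, cm = 0L,
                    bp = seq_len(M))
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ph <- ifelse(is.na(panel$phenotype), 0L, panel$phenotype + 1L)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(panel$dosages))) {
    d <- panel$dosages[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, "G", "A"))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, "G", "A"))
    writeLines(paste(c(panel$sample_ids[i], panel$sample_ids[i], 0L, 0L,
                       0L, ph[i], as.vector(rbind(a1, a2))),
                     collapse = " "), con)
  }
  invisible(prefix)
}

#' Simulate a multi-SNP case/control panel
#'
#' Independent SNPs in Hardy-Weinberg proportions at the given MAFs with a
#' phenotype assigned independently of genotype (a null panel), used for
#' bootstrap (h, f) estimation and scan benchmarking.
#'
#' @param n_individuals,n_cases sample sizes.
#' @param mafs per-SNP minor allele frequencies (recycled to `n_snps`).
#' @param n_snps number of SNPs.
#' @param seed integer seed.
#' @return A `genotype_panel`.
#' @export
simulate_panel <- function(n_individuals = 1000L, n_cases = 500L,
                           mafs = 0.4, n_snps = 50L, seed = 1L) {
  stopifnot(n_cases <= n_individuals)
  mafs <- rep_len(mafs, n_snps)
  set.seed(derive_seed(seed, 0L))
  dos <- vapply(mafs, function(m) stats::rbinom(n_individuals, 2L, m),
                integer(n_individuals))
  ph <- sample(rep(c(1L, 0L), c(n_cases, n_individuals - n_cases)))
  genotype_panel(dos, phenotype = ph)
}

#' Pairwise scan over all SNP pairs of a panel
#'
#' Runs the selected tests on every unordered SNP pair (upper-triangular
#' `i < j` order). When `hf_mode = "bootstrap"`, the W-test's (h, f)
#' parameters are estimated once from the whole panel via [bootstrap_hf()]
#' and reused for every pair.
#'
#' @param panel a `genotype_panel` with phenotype present.
#' @param tests test names (see [run_tests()]).
#' @param hf_mode `"default"`, `"fixed"` or `"bootstrap"`.
#' @param hf an `hf_set` when `hf_mode = "fixed"`.
#' @param seed seed for the bootstrap.
#' @param B bootstrap replicates for `hf_mode = "bootstrap"`.
#' @return Data frame with one row per pair per test: `snp1`, `snp2`,
#'   `test`, `statistic`, `df`, `p_value`, `defined`.
#' @export
scan_pairs <- function(panel, tests = c("W", "CHI-f", "CHI-r", "LR8"),
                       hf_mode = c("default", "fixed", "bootstrap"),
                       hf = NULL, seed = 1L, B = 200L) {
  stopifnot(inherits(panel, "genotype_panel"))
  hf_mode <- match.arg(hf_mode)
  if (all(is.na(panel$phenotype))) stop("panel has no phenotype")
  M <- ncol(panel$dosages)
  if (M < 2L) stop("need at least 2 SNPs")
  use_hf <- switch(hf_mode,
                   default = NULL,
                   fixed = {
                     if (is.null(hf)) stop("hf_mode = 'fixed' needs hf")
                     hf
                   },
                   bootstrap = bootstrap_hf(panel$dosages,
                                            n_cases = sum(panel$phenotype == 1L,
                                                          na.rm = TRUE),
                                            B = B, seed = seed))
  rows <- vector("list", M * (M - 1L) / 2L)
  r <- 0L
  for (i in seq_len(M - 1L)) {
    for (j in (i + 1L):M) {
      tab <- tryCatch(build_table(panel$dosages[, i], panel$dosages[, j],
                                  panel$phenotype),
                      error = function(e) NULL)
      res <- if (is.null(tab)) {
        lapply(tests, function(t) test_result(t, note = "no complete records"))
      } else {
        lapply(tests, function(t)
          tryCatch(run_tests(tab, t, hf = use_hf)[[1L]],
                   error = function(e) test_result(t, note = conditionMessage(e))))
      }
      r <- r + 1L
      rows[[r]] <- data.frame(
        snp1 = panel$snp_ids[i], snp2 = panel$snp_ids[j],
        test = tests,
        statistic = vapply(res, `[[`, numeric(1), "statistic"),
        df = vapply(res, `[[`, numeric(1), "df"),
        p_value = vapply(res, `[[`, numeric(1), "p_value"),
        defined = vapply(res, `[[`, logical(1), "defined"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a scan results table with a metadata header
#'
#' P-values are printed in scientific notation with 6 significant digits;
#' undefined results print as `NA`.
#'
#' @param results data frame from [scan_pairs()].
#' @param path output file.
#' @param header named character vector of metadata lines.
#' @export
write_results <- function(results, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(header))
    writeLines(sprintf("# %s: %s", nm, header[[nm]]), con)
  fmt <- results
  fmt$p_value <- ifelse(is.na(results$p_value), "NA",
                        sprintf("%.6e", results$p_value))
  utils::write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
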