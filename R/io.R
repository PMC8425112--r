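#' Read a subject-level table from CSV, TSV or PLINK .raw
#'
#' Delimited files need a header with unique names; missing-value tokens
#' \code{""}, \code{"NA"} and \code{"."} are normalised to NA. The PLINK
#' \code{.raw} dialect is whitespace-delimited with the six fixed columns
#' FID/IID/PAT/MAT/SEX/PHENOTYPE followed by 0/1/2 dosage columns, which
#' are validated on load. A load report (rows, missing counts per column)
#' is attached as the \code{"load_report"} attribute and logged.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"csv"}, \code{"tsv"}
#'   or \code{"plink_raw"}.
#' @param quiet suppress the load-report message.
#' @return A data frame.
#' @export
read_subject_table <- function(path, format = c("auto", "csv", "tsv",
                                                "plink_raw"),
                               quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     raw = "plink_raw",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format=", call. = FALSE))
  }
  na_tokens <- c("", "NA", ".")
  if (format == "plink_raw") {
    d <- utils::read.table(path, header = TRUE, na.strings = na_tokens,
                           check.names = FALSE, stringsAsFactors = FALSE)
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(d) < 7L || !identical(names(d)[1:6], fixed))
      stop("not a PLINK .raw file: expected leading columns ",
           paste(fixed, collapse = " "), call. = FALSE)
    dosage <- names(d)[-(1:6)]
    for (cn in dosage) {
      v <- d[[cn]]
      bad <- which(!is.na(v) & !v %in% c(0, 1, 2))
      if (length(bad))
        stop("dosage column '", cn, "' has values outside 0/1/2 at line(s) ",
             paste(utils::head(bad + 1L, 5L), collapse = ", "),
             call. = FALSE)
    }
  } else {
    sep <- if (format == "csv") "," else "\t"
    header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
    header <- gsub("^\"|\"$", "", header)
    if (anyDuplicated(header))
      stop("duplicate column name(s) in header (line 1): ",
           paste(unique(header[duplicated(header)]), collapse = ", "),
           call. = FALSE)
    nf <- utils::count.fields(path, sep = sep, quote = "\"")
    ragged <- which(nf != length(header))
    if (length(ragged))
      stop("non-rectangular rows (wrong field count) at line(s): ",
           paste(utils::head(ragged, 5L), collapse = ", "), call. = FALSE)
    d <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na_tokens, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE)
  }
  report <- list(n_rows = nrow(d),
                 n_missing = vapply(d, function(x) sum(is.na(x)), 0L))
  attr(d, "load_report") <- report
  if (!quiet)
    message(sprintf("read %d rows x %d columns from %s (%d missing values)",
                    nrow(d), ncol(d), basename(path),
                    sum(report$n_missing)))
  d
}

#' Format p-values in 3-significant-digit scientific notation
#'
#' @param p numeric vector of p-values.
#' @return Character vector like \code{"3.60e-04"}; NA stays \code{"NA"}.
#' @export
format_pvalue <- function(p) {
  out <- ifelse(is.na(p), "NA", sprintf("%.2e", p))
  out
}

#' Write batch results as TSV
#'
#' One row per SNP-environment pair (SNP, Environment, major/minor
#' alleles, MAF, best SNP mode and its p-value, selected interaction
#' pattern and its p-value, significance flag at the Bonferroni-corrected
#' level) plus selection metadata in header comments.
#'
#' @param batch an \code{\link{snpxe_batch}} result.
#' @param path output path.
#' @export
write_batch_tsv <- function(batch, path) {
  stopifnot(inherits(batch, "snpxe_batch"))
  tab <- batch$results
  tab$MAF <- sprintf("%.6g", tab$MAF)
  tab$p_SNPiv <- format_pvalue(tab$p_SNPiv)
  tab$p_int <- format_pvalue(tab$p_int)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# selection=%s family=%s alpha=%g m_tests=%d alpha_corrected=%g",
    batch$selection_rule, batch$family, batch$alpha, batch$m_tests,
    batch$alpha_corrected), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write the per-pattern long table for one pair as TSV
#'
#' One row per enumerated pattern (27 ordinal / 18 categorical) with its
#' BIC and overall interaction p-value, in the canonical pattern order.
#'
#' @param pair an \code{\link{snpxe_pair}} result.
#' @param path output path.
#' @export
write_all_fits_tsv <- function(pair, path) {
  stopifnot(inherits(pair, "snpxe_pair"))
  tab <- .pair_table(pair)
  tab$selected <- !pair$failed & tab$pattern == pair$best$spec$label
  tab$bic <- sprintf("%.6g", tab$bic)
  tab$p_interaction <- format_pvalue(tab$p_interaction)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

## minimal JSON writer for the run-metadata sidecar (flat lists only)
.to_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  one <- function(v) {
    if (is.null(v)) return("null")
    if (is.list(v))
      return(paste0("{", paste0('"', esc(names(v)), '": ',
                                vapply(v, one, ""), collapse = ", "), "}"))
    if (length(v) != 1L)
      return(paste0("[", paste(vapply(v, one, ""), collapse = ", "), "]"))
    if (is.character(v)) paste0('"', esc(v), '"')
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 15)
  }
  one(x)
}

.cli_usage <- function() {
  paste(
    "usage: snpxe <subcommand> [options]",
    "",
    "subcommands:",
    "  pair      pattern search for one SNP-environment pair",
    "  batch     pattern search across SNPs with Bonferroni correction",
    "  grid      outcome-proportion grid for a pair",
    "  maf       allele/MAF summary for a SNP column",
    "  main      SNP main-effect test under three inheritance modes",
    "  simulate  generate a synthetic cohort with planted interactions",
    "",
    "common options:",
    "  --data PATH          input table (.csv/.tsv/.raw)",
    "  --outcome NAME       phenotype column",
    "  --env NAME           environmental factor column",
    "  --snp NAME           SNP column (pair/grid/maf/main)",
    "  --snps A,B,C         SNP columns (batch)",
    "  --env-type T         ordinal (default) | categorical",
    "  --family F           binary (default) | continuous",
    "  --selection S        bic (default) | pvalue",
    "  --covariates A,B     covariate columns",
    "  --alpha X            family-wise level for batch (default 0.05)",
    "  --all-fits PATH      also write the per-pattern long table",
    "  --out PATH           output file",
    "simulate options:",
    "  --n N                subjects (default 2000)",
    "  --seed S             integer seed",
    sep = "\n")
}

.cli_parse <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag --", key, " needs a value", call. = FALSE)
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line interface
#'
#' Thin shell over the package's functions; used by the installed
#' \code{inst/cli/snpxe.R} wrapper script. Returns (invisibly) an exit
#' code: 0 on success, 2 on a usage or validation error.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
snpxe_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  run <- function() {
    if (length(args) == 0L || args[1] %in% c("-h", "--help", "help")) {
      cat(.cli_usage(), "\n")
      return(0L)
    }
    sub <- args[1]
    valid <- c("pair", "batch", "grid", "maf", "main", "simulate")
    if (!sub %in% valid)
      stop("unknown subcommand '", sub, "'", call. = FALSE)
    fl <- .cli_parse(args[-1])
    known <- c("data", "outcome", "env", "snp", "snps", "env-type", "family",
               "selection", "covariates", "alpha", "all-fits", "out", "n",
               "seed")
    unk <- setdiff(names(fl), known)
    if (length(unk))
      stop("unknown flag(s): ", paste0("--", unk, collapse = ", "),
           call. = FALSE)
    need <- function(key) {
      if (is.null(fl[[key]])) stop("--", key, " is required for '", sub, "'",
                                   call. = FALSE)
      fl[[key]]
    }
    covars <- if (is.null(fl$covariates)) NULL else
      strsplit(fl$covariates, ",", fixed = TRUE)[[1]]
    family <- switch(if (is.null(fl$family)) "binary" else fl$family,
                     binary = "logistic", continuous = "linear",
                     stop("--family must be binary or continuous",
                          call. = FALSE))
    env_type <- if (is.null(fl$`env-type`)) "ordinal" else fl$`env-type`
    selection <- if (is.null(fl$selection)) "bic" else fl$selection

    if (sub == "simulate") {
      n <- if (is.null(fl$n)) 2000L else as.integer(fl$n)
      seed <- if (is.null(fl$seed)) NULL else as.integer(fl$seed)
      out <- need("out")
      d <- make_simdata2_like(seed = seed, n = n)
      utils::write.csv(d, out, row.names = FALSE, quote = FALSE)
      meta <- list(subcommand = "simulate", n = n,
                   seed = if (is.null(seed)) "none" else seed,
                   columns = names(d), truth = attr(d, "truth"))
      writeLines(.to_json(meta), paste0(out, ".meta.json"))
      message("wrote ", out, " and ", out, ".meta.json")
      return(0L)
    }

    d <- read_subject_table(need("data"))
    if (sub == "maf") {
      print(maf_info(d[[need("snp")]], snp_name = fl$snp))
      return(0L)
    }
    if (sub == "main") {
      print(snp_main(d, need("snp"), need("outcome"), family, covars))
      return(0L)
    }
    if (sub == "grid") {
      g <- grid_proportions(d, need("snp"), need("env"), need("outcome"))
      print(g)
      if (!is.null(fl$out)) {
        utils::write.table(.grid_text(g), fl$out, sep = "\t", quote = FALSE,
                           col.names = NA)
        message("wrote ", fl$out)
      }
      return(0L)
    }
    if (sub == "pair") {
      pr <- snpxe_pair(d, need("snp"), need("env"), need("outcome"),
                       env_type, family, covars, selection)
      print(summary(pr))
      if (!is.null(fl$`all-fits`)) {
        write_all_fits_tsv(pr, fl$`all-fits`)
        message("wrote ", fl$`all-fits`)
      }
      return(if (pr$failed) 2L else 0L)
    }
    ## batch
    snps <- strsplit(need("snps"), ",", fixed = TRUE)[[1]]
    alpha <- if (is.null(fl$alpha)) 0.05 else as.numeric(fl$alpha)
    b <- snpxe_batch(d, snps, need("env"), need("outcome"), env_type,
                     family, covars, selection, alpha = alpha)
    print(b)
    if (!is.null(fl$out)) {
      write_batch_tsv(b, fl$out)
      message("wrote ", fl$out)
    }
    0L
  }
  code <- tryCatch(run(), error = function(e) {
    message("error: ", conditionMessage(e))
    message(.cli_usage())
    2L
  })
  invisible(code)
}
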