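#' Allele and minor-allele-frequency summary for one SNP
#'
#' Accepts either unordered allele-pair strings ("AG" is the same genotype
#' as "GA") or numeric minor-allele counts 0/1/2. Allele frequencies are
#' counted over non-missing subjects (two alleles each); the minor allele
#' is the less frequent one (frequency tie: the alphabetically later allele
#' is called minor). Numeric input yields \code{maf = mean/2} with alleles
#' unnamed.
#'
#' @param genotype_col vector of 2-character allele strings or 0/1/2 counts.
#' @param snp_name label carried into the result.
#' @return Object of class \code{"snp_info"}: \code{major_allele},
#'   \code{minor_allele}, \code{maf}, \code{missing_pct} (0-100),
#'   \code{monomorphic}, \code{n}.
#' @examples
#' maf_info(c(rep("AA", 60), rep("AG", 30), rep("GG", 10)))$maf  # 0.25
#' @export
maf_info <- function(genotype_col, snp_name = deparse(substitute(genotype_col))) {
  if (length(genotype_col) == 0L)
    stop("empty genotype column", call. = FALSE)
  n <- length(genotype_col)
  if (is.factor(genotype_col)) genotype_col <- as.character(genotype_col)
  out <- list(snp_name = snp_name, major_allele = NA_character_,
              minor_allele = NA_character_, maf = NA_real_,
              missing_pct = NA_real_, monomorphic = FALSE, n = n)
  class(out) <- "snp_info"
  if (is.character(genotype_col)) {
    g <- toupper(trimws(genotype_col))
    g[g %in% c("", "NA", ".")] <- NA
    ok <- !is.na(g)
    if (!all(nchar(g[ok]) == 2L))
      stop("allele-string genotypes must be 2-character pairs (e.g. \"AG\")",
           call. = FALSE)
    if (!any(ok)) stop("genotype column is all missing", call. = FALSE)
    alleles <- unlist(strsplit(g[ok], ""))
    counts <- sort(table(alleles), decreasing = TRUE)
    if (length(counts) > 2L)
      stop("SNP '", snp_name, "' is multi-allelic (",
           paste(names(counts), collapse = ", "), ")", call. = FALSE)
    if (length(counts) == 1L) {
      out$major_allele <- names(counts)[1L]
      out$minor_allele <- NA_character_
      out$maf <- 0
      out$monomorphic <- TRUE
    } else {
      nm <- names(counts)
      if (counts[1L] == counts[2L]) nm <- sort(nm)  # tie: later allele minor
      out$major_allele <- nm[1L]
      out$minor_allele <- nm[2L]
      out$maf <- as.numeric(counts[[nm[2L]]]) / (2 * sum(ok))
    }
    out$missing_pct <- 100 * mean(!ok)
  } else {
    g <- as.numeric(genotype_col)
    ok <- !is.na(g)
    bad <- which(ok & !g %in% c(0, 1, 2))
    if (length(bad))
      stop("numeric genotypes must be 0/1/2 minor-allele counts; offending row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    if (!any(ok)) stop("genotype column is all missing", call. = FALSE)
    out$maf <- mean(g[ok]) / 2
    out$missing_pct <- 100 * mean(!ok)
    vals <- unique(g[ok])
    out$monomorphic <- length(vals) == 1L && vals %in% c(0, 2)
  }
  out
}

#' @export
print.snp_info <- function(x, ...) {
  cat(sprintf("SNP %s: major/minor = %s/%s, MAF = %.3f, missing = %.1f%%%s\n",
              x$snp_name,
              ifelse(is.na(x$major_allele), "?", x$major_allele),
              ifelse(is.na(x$minor_allele), "?", x$minor_allele),
              x$maf, x$missing_pct,
              if (x$monomorphic) " [monomorphic]" else ""))
  invisible(x)
}

#' Recode allele-pair genotypes to minor-allele counts
#'
#' @param genotype_col allele-string genotypes (or 0/1/2, returned
#'   validated as-is).
#' @param info the \code{\link{maf_info}} result for the same column.
#' @return Integer vector of minor-allele counts 0/1/2 (NA preserved).
#' @export
recode_minor_count <- function(genotype_col, info) {
  stopifnot(inherits(info, "snp_info"))
  if (is.numeric(genotype_col)) {
    bad <- which(!is.na(genotype_col) & !genotype_col %in% c(0, 1, 2))
    if (length(bad))
      stop("numeric genotypes must be 0/1/2; offending row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    return(as.integer(genotype_col))
  }
  if (is.factor(genotype_col)) genotype_col <- as.character(genotype_col)
  g <- toupper(trimws(genotype_col))
  g[g %in% c("", "NA", ".")] <- NA
  known <- c(info$major_allele, info$minor_allele)
  known <- known[!is.na(known)]
  out <- rep(NA_integer_, length(g))
  ok <- !is.na(g)
  al <- strsplit(g[ok], "")
  bad <- vapply(al, function(a) !all(a %in% known), logical(1))
  if (any(bad))
    stop("allele(s) not matching major/minor (", paste(known, collapse = "/"),
         ") at row(s): ",
         paste(utils::head(which(ok)[bad], 5L), collapse = ", "),
         call. = FALSE)
  out[ok] <- vapply(al, function(a)
    if (is.na(info$minor_allele)) 0L else sum(a == info$minor_allele),
    integer(1))
  out
}

#' SNP main-effect test under the three inheritance modes
#'
#' Fits phenotype ~ coded SNP (+ covariates) once per inheritance mode
#' (additive, dominant, recessive, original direction) and reports the Wald
#' p-value of the SNP coefficient for each. The best mode is the one with
#' the smallest p-value (ties go to additive); \code{p_SNPiv} is that
#' smallest p — the SNP's individual-effect p-value. \code{mode_select =
#' "bic"} picks the smallest-BIC mode instead.
#'
#' @inheritParams snpxe_pair
#' @param mode_select \code{"pvalue"} (default) or \code{"bic"}.
#' @return Object of class \code{"snp_main"}: \code{per_mode} data frame
#'   (mode, coefficient, se, p, bic), \code{best_mode}, \code{p_SNPiv},
#'   \code{monomorphic}.
#' @export
snp_main <- function(data, snp, outcome, family = c("logistic", "linear"),
                     covariates = NULL, mode_select = c("pvalue", "bic")) {
  family <- match.arg(family)
  mode_select <- match.arg(mode_select)
  cols <- c(outcome, snp, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  keep <- .complete_rows(data, cols)
  d <- data[keep, , drop = FALSE]
  modes <- c("additive", "dominant", "recessive")
  cv <- if (is.null(covariates)) NULL else
    as.matrix(d[, covariates, drop = FALSE])
  per <- data.frame(mode = modes, coefficient = NA_real_, se = NA_real_,
                    p = NA_real_, bic = NA_real_, stringsAsFactors = FALSE)
  mono <- length(unique(d[[snp]][!is.na(d[[snp]])])) <= 1L
  if (!mono) {
    for (i in seq_along(modes)) {
      s <- code_snp(d[[snp]], modes[i], "original")
      if (length(unique(s)) < 2L) next  # e.g. no homozygous-minor subjects
      X <- cbind(`(Intercept)` = 1, SNP = s, cv)
      f <- fit_glm(X, d[[outcome]], family)
      if (!f$estimable) next
      per$coefficient[i] <- f$coefficients[["SNP"]]
      per$se[i] <- f$se[["SNP"]]
      per$p[i] <- 2 * stats::pnorm(-abs(per$coefficient[i] / per$se[i]))
      per$bic[i] <- bic(f)
    }
  }
  key <- if (mode_select == "pvalue") per$p else per$bic
  best <- if (all(is.na(key))) NA_integer_ else which.min(key)  # first min: additive wins ties
  structure(list(snp_name = snp, per_mode = per,
                 best_mode = if (is.na(best)) NA_character_ else modes[best],
                 p_SNPiv = if (is.na(best)) NA_real_ else per$p[best],
                 monomorphic = mono, n_used = nrow(d), family = family),
            class = "snp_main")
}

#' @export
print.snp_main <- function(x, ...) {
  cat(sprintf("SNP main effect for %s (%s family, n = %d)%s\n", x$snp_name,
              x$family, x$n_used,
              if (x$monomorphic) " [monomorphic: no test]" else ""))
  tab <- x$per_mode
  tab$p <- format_pvalue(tab$p)
  tab$bic <- round(tab$bic, 2)
  print(tab, row.names = FALSE)
  if (!is.na(x$best_mode))
    cat(sprintf("best mode: %s (p_SNPiv = %s)\n", x$best_mode,
                format_pvalue(x$p_SNPiv)))
  invisible(x)
}

#' Outcome-proportion grid by genotype and environment level
#'
#' For a binary phenotype, tabulates the outcome proportion (disease
#' prevalence D%) and cell size for every genotype (rows 0/1/2, always all
#' three) by environment level (observed levels) combination, on complete
#' cases. Cells with no subjects get n = 0 and a missing proportion.
#'
#' @inheritParams snpxe_pair
#' @return Object of class \code{"snpxe_grid"}: \code{proportions} and
#'   \code{n} matrices, \code{overall_n}, \code{prevalence}.
#' @export
grid_proportions <- function(data, snp, env, outcome) {
  cols <- c(outcome, snp, env)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  keep <- .complete_rows(data, cols)
  d <- data[keep, , drop = FALSE]
  y <- d[[outcome]]
  if (!all(y %in% c(0, 1)))
    stop("outcome-proportion grids are defined for binary (0/1) outcomes",
         call. = FALSE)
  g <- d[[snp]]
  bad <- which(!g %in% c(0, 1, 2))
  if (length(bad))
    stop("genotypes must be 0/1/2 minor-allele counts; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  levs <- sort(unique(d[[env]]))
  geno <- c(0, 1, 2)
  prop <- nmat <- matrix(NA_real_, 3L, length(levs),
                         dimnames = list(genotype = as.character(geno),
                                         env = as.character(levs)))
  for (i in seq_along(geno)) for (j in seq_along(levs)) {
    sel <- g == geno[i] & d[[env]] == levs[j]
    nmat[i, j] <- sum(sel)
    prop[i, j] <- if (any(sel)) mean(y[sel]) else NA_real_
  }
  structure(list(proportions = prop, n = nmat,
                 overall_n = nrow(d), prevalence = mean(y),
                 snp_name = snp, env_name = env, outcome_name = outcome),
            class = "snpxe_grid")
}

## "D% (n)" cell text, Fig-style: prevalence as a percentage
.grid_text <- function(grid) {
  txt <- matrix("", nrow(grid$n), ncol(grid$n), dimnames = dimnames(grid$n))
  for (i in seq_len(nrow(txt))) for (j in seq_len(ncol(txt))) {
    txt[i, j] <- if (grid$n[i, j] == 0) "- (0)" else
      sprintf("%.1f%% (%d)", 100 * grid$proportions[i, j], grid$n[i, j])
  }
  txt
}

## cells in the pattern-implied reference group: coded SNP 0 or reference
## environment level (interaction contribution is zero there)
.reference_cells <- function(grid, spec, env_type = "ordinal") {
  s_coded <- code_snp(c(0, 1, 2), spec$mode, spec$snp_dir)
  levs <- colnames(grid$n)
  num <- suppressWarnings(as.numeric(levs))
  if (!anyNA(num)) levs <- num
  ec <- code_env(levs, spec$env_dir, env_type)
  ref_env <- as.character(ec$reference)
  ref <- matrix(FALSE, nrow(grid$n), ncol(grid$n), dimnames = dimnames(grid$n))
  for (i in 1:3) for (j in seq_len(ncol(ref)))
    ref[i, j] <- s_coded[i] == 0 || colnames(ref)[j] == ref_env
  ref
}

#' Render a heat-table of outcome proportions
#'
#' Colour-scaled genotype-by-environment table annotated with "D% (n)" per
#' cell; the colour scale is linear in the proportion over observed cells.
#' When a pattern is supplied, the reference sub-groups it implies (cells
#' whose interaction contribution is zero) are framed. A plain-text table
#' is always returned; a figure is drawn on the current device, or written
#' to \code{file} (.png, .svg or .pdf).
#'
#' @param grid an \code{\link{grid_proportions}} result.
#' @param highlight optional \code{pattern_spec} whose implied reference
#'   group is framed.
#' @param file optional figure path; extension selects the device.
#' @param draw draw the figure (default TRUE when a device is usable).
#' @return Invisibly, the character matrix of "D% (n)" cells.
#' @export
render_heattable <- function(grid, highlight = NULL, file = NULL,
                             draw = TRUE) {
  stopifnot(inherits(grid, "snpxe_grid"))
  txt <- .grid_text(grid)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 640, height = 480),
           svg = grDevices::svg(file, width = 7, height = 5),
           pdf = grDevices::pdf(file, width = 7, height = 5),
           stop("unsupported figure format: .", ext, call. = FALSE))
    on.exit(grDevices::dev.off(), add = TRUE)
    draw <- TRUE
  }
  if (draw) .draw_heattable(grid, txt, highlight)
  invisible(txt)
}

.draw_heattable <- function(grid, txt, highlight = NULL) {
  p <- grid$proportions
  nr <- nrow(p); nc <- ncol(p)
  rng <- range(p, na.rm = TRUE)
  if (!is.finite(rng[1])) rng <- c(0, 1)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(rng[1], 0.1)
  scale01 <- function(v) (v - rng[1]) / (rng[2] - rng[1])
  pal <- grDevices::colorRampPalette(c("#fff7f3", "#fb6a4a"))(101)
  graphics::plot(NULL, xlim = c(0.5, nc + 0.5), ylim = c(0.5, nr + 0.5),
                 xlab = grid$env_name, ylab = grid$snp_name,
                 axes = FALSE, asp = NA,
                 main = sprintf("Outcome proportions: %s x %s",
                                grid$snp_name, grid$env_name))
  graphics::axis(1, at = seq_len(nc), labels = colnames(p), tick = FALSE)
  graphics::axis(2, at = seq_len(nr), labels = rownames(p), tick = FALSE,
                 las = 1)
  ref <- if (!is.null(highlight))
    tryCatch(.reference_cells(grid, highlight), error = function(e) NULL)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    yy <- nr - i + 1  # genotype 0 on top
    col <- if (is.na(p[i, j])) "grey95" else
      pal[1 + round(100 * scale01(p[i, j]))]
    graphics::rect(j - 0.5, yy - 0.5, j + 0.5, yy + 0.5, col = col,
                   border = "grey70")
    graphics::text(j, yy, txt[i, j], cex = 0.9)
    if (!is.null(ref) && isTRUE(ref[i, j]))
      graphics::rect(j - 0.47, yy - 0.47, j + 0.47, yy + 0.47,
                     border = "black", lwd = 2.5)
  }
  invisible(NULL)
}

#' @export
print.snpxe_grid <- function(x, ...) {
  cat(sprintf("Outcome proportions by %s x %s (n = %d, prevalence = %.3f)\n",
              x$snp_name, x$env_name, x$overall_n, x$prevalence))
  print(.grid_text(x), quote = FALSE)
  invisible(x)
}

#' @export
plot.snpxe_grid <- function(x, highlight = NULL, ...) {
  render_heattable(x, highlight = highlight, ...)
}
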