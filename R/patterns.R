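#' @keywords internal
"_PACKAGE"

## Pattern family: model structure x SNP inheritance mode x risk directions.
## Labels follow the field grammar <structure>_<A|D|R>E_<oo|or|ro|rr>, where
## the first direction letter is the SNP's and the second the environment's.

.snpxe_structures <- c("Full", "Mint_SNP", "Mint_Env", "Int")
.snpxe_modes <- c(additive = "A", dominant = "D", recessive = "R")
.snpxe_dirs <- c(original = "o", reverse = "r")

## direction pairs admitted per structure; reversing a direction inside a
## structure that carries that factor's main effect spans the same column
## space, so those variants are redundant and excluded by design
.snpxe_dirpairs <- list(
  Full     = "oo",
  Mint_SNP = c("oo", "ro"),
  Mint_Env = c("oo", "or"),
  Int      = c("oo", "or", "ro", "rr")
)

#' Construct an interaction pattern specification
#'
#' A pattern is one combination of model structure, SNP inheritance mode and
#' the risk directions of the SNP and the environmental factor. Structures
#' that include a factor's main effect only admit the original direction for
#' that factor (the reversed design spans the same column space).
#'
#' @param structure one of \code{"Full"}, \code{"Mint_SNP"},
#'   \code{"Mint_Env"}, \code{"Int"}: which main effects accompany the
#'   interaction terms.
#' @param mode SNP inheritance mode: \code{"additive"}, \code{"dominant"} or
#'   \code{"recessive"}.
#' @param snp_dir,env_dir risk direction of each factor, \code{"original"}
#'   or \code{"reverse"}.
#' @return An object of class \code{"pattern_spec"} with the four components
#'   and the canonical \code{label}.
#' @examples
#' pattern_spec("Int", "recessive", "reverse", "original")$label  # "Int_RE_ro"
#' @export
pattern_spec <- function(structure, mode, snp_dir = "original",
                         env_dir = "original") {
  structure <- match.arg(structure, .snpxe_structures)
  mode <- match.arg(mode, names(.snpxe_modes))
  snp_dir <- match.arg(snp_dir, names(.snpxe_dirs))
  env_dir <- match.arg(env_dir, names(.snpxe_dirs))
  if (structure == "Full" && (snp_dir != "original" || env_dir != "original"))
    stop("Full structure admits only original directions for both factors",
         call. = FALSE)
  if (structure == "Mint_SNP" && env_dir != "original")
    stop("Mint_SNP structure admits only the original environment direction",
         call. = FALSE)
  if (structure == "Mint_Env" && snp_dir != "original")
    stop("Mint_Env structure admits only the original SNP direction",
         call. = FALSE)
  label <- paste0(structure, "_", .snpxe_modes[[mode]], "E_",
                  .snpxe_dirs[[snp_dir]], .snpxe_dirs[[env_dir]])
  structure(list(structure = structure, mode = mode, snp_dir = snp_dir,
                 env_dir = env_dir, label = label),
            class = "pattern_spec")
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat("SNPxE interaction pattern:", x$label, "\n")
  cat("  structure:", x$structure, "| mode:", x$mode,
      "| SNP direction:", x$snp_dir, "| env direction:", x$env_dir, "\n")
  invisible(x)
}

#' Enumerate the SNPxE interaction pattern family
#'
#' For an ordinal environmental factor the reference level may be the lowest
#' or the highest, so both environment directions are kept: 27 patterns.
#' For a categorical factor the reference is user-chosen, so the 9 patterns
#' whose label ends in \code{"_or"} or \code{"_rr"} are dropped: 18 patterns.
#'
#' The order is deterministic: structures \code{Full}, \code{Mint_SNP},
#' \code{Mint_Env}, \code{Int}; within a structure modes additive, dominant,
#' recessive; within a mode direction pairs \code{oo}, \code{or}, \code{ro},
#' \code{rr} as admitted.
#'
#' @param env_type \code{"ordinal"} or \code{"categorical"}.
#' @return A named list of \code{pattern_spec} objects (names are labels).
#' @examples
#' length(enumerate_patterns("ordinal"))      # 27
#' length(enumerate_patterns("categorical"))  # 18
#' @export
enumerate_patterns <- function(env_type = c("ordinal", "categorical")) {
  env_type <- match.arg(env_type)
  out <- list()
  for (structure in .snpxe_structures) {
    for (mode in names(.snpxe_modes)) {
      for (dp in .snpxe_dirpairs[[structure]]) {
        if (env_type == "categorical" && substr(dp, 2, 2) == "r") next
        sdir <- names(.snpxe_dirs)[match(substr(dp, 1, 1), .snpxe_dirs)]
        edir <- names(.snpxe_dirs)[match(substr(dp, 2, 2), .snpxe_dirs)]
        sp <- pattern_spec(structure, mode, sdir, edir)
        out[[sp$label]] <- sp
      }
    }
  }
  out
}

#' Canonical label of a pattern
#'
#' @param spec a \code{pattern_spec}.
#' @return The label string, e.g. \code{"Mint_Env_DE_or"}.
#' @export
pattern_label <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  spec$label
}

#' Parse a canonical pattern label
#'
#' Inverse of \code{\link{pattern_label}}: accepts exactly the 27 canonical
#' labels of the ordinal family.
#'
#' @param label a label such as \code{"Full_AE_oo"} or \code{"Int_RE_ro"}.
#' @return The corresponding \code{pattern_spec}.
#' @export
parse_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  fam <- enumerate_patterns("ordinal")
  if (!label %in% names(fam))
    stop("not a canonical pattern label: '", label, "'. Valid labels: ",
         paste(names(fam), collapse = ", "), call. = FALSE)
  fam[[label]]
}

#' Code a SNP genotype vector under an inheritance mode and direction
#'
#' Genotypes are minor-allele counts 0/1/2. Original codings: additive
#' 0,1,2; dominant 0,1,1 (minor-allele carrier); recessive 0,0,1 (homozygous
#' minor). Reverse codings complement the original: \code{2 - S} for
#' additive, \code{1 - S} for the binary modes. Missing values stay missing.
#'
#' @param genotypes integer-like vector with values in \{0,1,2\} or NA.
#' @param mode inheritance mode.
#' @param dir risk direction.
#' @return Numeric vector of the coded SNP.
#' @examples
#' code_snp(c(0, 1, 2), "recessive", "original")  # 0 0 1
#' @export
code_snp <- function(genotypes, mode = c("additive", "dominant", "recessive"),
                     dir = c("original", "reverse")) {
  mode <- match.arg(mode)
  dir <- match.arg(dir)
  g <- as.numeric(genotypes)
  bad <- which(!is.na(g) & !g %in% c(0, 1, 2))
  if (length(bad))
    stop("genotype values outside {0,1,2,NA} at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  s <- switch(mode,
              additive  = g,
              dominant  = as.numeric(g >= 1),
              recessive = as.numeric(g == 2))
  if (dir == "reverse") s <- (if (mode == "additive") 2 else 1) - s
  s
}

#' Build indicator (dummy) columns for the environmental factor
#'
#' One indicator per non-reference level, ordered by level. For an ordinal
#' factor the reference is the lowest level under the original direction and
#' the highest under the reverse direction. For a categorical factor only
#' the original direction is defined and the reference defaults to the first
#' level in sort order unless supplied.
#'
#' @param env vector of environment levels (ordinal codes or category
#'   labels); NAs are propagated.
#' @param dir risk direction; must be \code{"original"} for categorical.
#' @param env_type \code{"ordinal"} or \code{"categorical"}.
#' @param reference optional reference level (categorical only).
#' @return A list with \code{dummies} (n x (k-1) indicator matrix, columns
#'   named \code{ENV_<level>vs<ref>}), \code{reference} and \code{levels}
#'   (all observed levels, sorted).
#' @export
code_env <- function(env, dir = c("original", "reverse"),
                     env_type = c("ordinal", "categorical"),
                     reference = NULL) {
  dir <- match.arg(dir)
  env_type <- match.arg(env_type)
  levs <- sort(unique(env[!is.na(env)]))
  if (length(levs) < 2L)
    stop("environmental factor has fewer than 2 observed levels",
         call. = FALSE)
  if (env_type == "categorical") {
    if (dir == "reverse")
      stop("reverse direction is not defined for a categorical environment ",
           "(the reference level is user-chosen)", call. = FALSE)
    ref <- if (is.null(reference)) levs[1L] else reference
    if (!ref %in% levs) stop("reference level '", ref, "' not observed",
                             call. = FALSE)
  } else {
    ref <- if (dir == "original") levs[1L] else levs[length(levs)]
  }
  nonref <- levs[levs != ref]
  dummies <- vapply(nonref, function(l) as.numeric(env == l),
                    numeric(length(env)))
  dummies <- matrix(dummies, nrow = length(env),
                    dimnames = list(NULL, paste0("ENV_", nonref, "vs", ref)))
  list(dummies = dummies, reference = ref, levels = levs)
}

#' Assemble the design matrix for a model structure
#'
#' Always includes an intercept and every interaction column (coded SNP
#' times each environment indicator); main-effect columns follow the
#' structure: \code{Full} keeps both, \code{Mint_SNP} the SNP only,
#' \code{Mint_Env} the environment only, \code{Int} neither. Covariates, if
#' any, are appended.
#'
#' @param snp_coded coded SNP vector (see \code{\link{code_snp}}).
#' @param env_dummies indicator matrix from \code{\link{code_env}}.
#' @param structure model structure.
#' @param covariates optional numeric matrix or data frame of covariates.
#' @return A list with \code{design} (matrix incl. intercept),
#'   \code{interaction_cols} (their column names), \code{main_snp} /
#'   \code{main_env} flags and \code{estimable} (FALSE when some
#'   non-intercept column is constant).
#' @export
build_design <- function(snp_coded, env_dummies, structure = .snpxe_structures,
                         covariates = NULL) {
  structure <- match.arg(structure)
  n <- length(snp_coded)
  stopifnot(nrow(env_dummies) == n)
  inter <- snp_coded * env_dummies
  colnames(inter) <- paste0("SNP:", colnames(env_dummies))
  main_snp <- structure %in% c("Full", "Mint_SNP")
  main_env <- structure %in% c("Full", "Mint_Env")
  parts <- list(`(Intercept)` = rep(1, n))
  if (main_snp) parts$SNP <- snp_coded
  X <- do.call(cbind, parts)
  if (main_env) X <- cbind(X, env_dummies)
  X <- cbind(X, inter)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (is.null(colnames(cv)))
      colnames(cv) <- paste0("covar", seq_len(ncol(cv)))
    stopifnot(nrow(cv) == n)
    X <- cbind(X, cv)
  }
  nonconst <- apply(X[, -1L, drop = FALSE], 2L,
                    function(col) {
                      r <- range(col, na.rm = TRUE)
                      is.finite(r[1]) && r[1] < r[2]
                    })
  list(design = X, interaction_cols = colnames(inter),
       main_snp = main_snp, main_env = main_env,
       estimable = all(nonconst))
}
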