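#' Feature-engineering configuration
#'
#' Controls which candidate covariates are generated from the original
#' environmental covariates: pairwise arithmetic combinations of every
#' unordered covariate pair and unary transformations of each single
#' covariate.
#'
#' @param pairwise_ops Subset of `c("add","sub","mul","div")`; default all.
#' @param unary_ops Subset of `c("inverse","square","sqrt","log","boxcox")`;
#'   default all.
#' @param boxcox_lambdas Box-Cox exponents; `(x^lambda - 1)/lambda` is emitted
#'   once per lambda for each eligible (strictly positive) covariate. Lambda 0
#'   is excluded (the log transform covers it) and 1 is excluded (identity).
#'   Defaults to `c(0.25, 0.75, 1.5)`: lambdas -1, 0.5 and 2 are omitted
#'   because they duplicate the inverse/sqrt/square transforms up to an affine
#'   map, to which Pearson-based selection is invariant.
#' @param zero_tolerance Denominators and inverse arguments must exceed this
#'   in absolute value for the ratio/inverse column to be emitted.
#' @return An object of class `fe_config`.
#' @export
fe_config <- function(pairwise_ops = c("add", "sub", "mul", "div"),
                      unary_ops = c("inverse", "square", "sqrt", "log", "boxcox"),
                      boxcox_lambdas = c(0.25, 0.75, 1.5),
                      zero_tolerance = 1e-12) {
  if (length(pairwise_ops)) {
    pairwise_ops <- match.arg(pairwise_ops, c("add", "sub", "mul", "div"),
                              several.ok = TRUE)
  }
  if (length(unary_ops)) {
    unary_ops <- match.arg(unary_ops, c("inverse", "square", "sqrt", "log", "boxcox"),
                           several.ok = TRUE)
  }
  if (any(boxcox_lambdas %in% c(0, 1))) {
    stop("boxcox_lambdas must exclude 0 (use log) and 1 (identity)", call. = FALSE)
  }
  structure(list(pairwise_ops = pairwise_ops, unary_ops = unary_ops,
                 boxcox_lambdas = boxcox_lambdas, zero_tolerance = zero_tolerance),
            class = "fe_config")
}

new_fe_block <- function(env_ids, cols, names, provenance, skipped) {
  if (length(cols) == 0L) {
    W <- matrix(numeric(0), nrow = length(env_ids), ncol = 0L,
                dimnames = list(env_ids, character(0)))
    out <- env_covariate_table(W, provenance = character(0))
  } else {
    W <- do.call(cbind, cols)
    dimnames(W) <- list(env_ids, names)
    out <- env_covariate_table(W, provenance = provenance)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Pairwise arithmetic combinations of environmental covariates
#'
#' For each unordered pair of original covariates \{a, b\} (a before b in
#' column order) emits one column per enabled operation: `a + b`, `a - b`,
#' `a * b` and `a / b`. The ratio is emitted only when every `|b|` exceeds
#' `zero_tolerance`; skipped ratios are recorded in the `skipped` attribute.
#'
#' @param W An `env_covariate_table` of original covariates.
#' @param cfg An [fe_config()].
#' @return An `env_covariate_table` holding only the new columns (provenance
#'   `"pairwise:<op>:<a>:<b>"`), at most `4 * choose(q, 2)` of them.
#' @export
pairwise_features <- function(W, cfg = fe_config()) {
  stopifnot(inherits(W, "env_covariate_table"), inherits(cfg, "fe_config"))
  q <- ncol(W)
  env_ids <- rownames(W)
  cols <- list(); nms <- character(0); prov <- character(0); skipped <- character(0)
  if (q >= 2L) {
    cn <- colnames(W)
    for (i in seq_len(q - 1L)) for (j in seq.int(i + 1L, q)) {
      a <- W[, i]; b <- W[, j]
      for (op in cfg$pairwise_ops) {
        if (op == "div" && min(abs(b)) <= cfg$zero_tolerance) {
          skipped <- c(skipped, sprintf("pairwise:div:%s:%s (denominator ~ 0)", cn[i], cn[j]))
          next
        }
        v <- switch(op, add = a + b, sub = a - b, mul = a * b, div = a / b)
        cols[[length(cols) + 1L]] <- v
        nms <- c(nms, paste(cn[i], op, cn[j], sep = "_"))
        prov <- c(prov, sprintf("pairwise:%s:%s:%s", op, cn[i], cn[j]))
      }
    }
  }
  new_fe_block(env_ids, cols, nms, prov, skipped)
}

#' Unary transformations of environmental covariates
#'
#' Per original covariate `x`: the square is always emitted; the inverse is
#' emitted iff every `|x|` exceeds `zero_tolerance`; square root, natural log
#' and the Box-Cox transforms `(x^lambda - 1)/lambda` are emitted iff `x` is
#' strictly positive. Ineligible transforms are skipped (never shifted) and
#' recorded in the `skipped` attribute.
#'
#' @inheritParams pairwise_features
#' @return An `env_covariate_table` of new columns only (provenance
#'   `"unary:<op>:<x>"`, Box-Cox as `"unary:boxcox<lambda>:<x>"`).
#' @export
unary_features <- function(W, cfg = fe_config()) {
  stopifnot(inherits(W, "env_covariate_table"), inherits(cfg, "fe_config"))
  env_ids <- rownames(W)
  cols <- list(); nms <- character(0); prov <- character(0); skipped <- character(0)
  cn <- colnames(W)
  for (i in seq_len(ncol(W))) {
    x <- W[, i]
    pos <- min(x) > 0
    nonzero <- min(abs(x)) > cfg$zero_tolerance
    for (op in cfg$unary_ops) {
      if (op == "inverse" && !nonzero) {
        skipped <- c(skipped, sprintf("unary:inverse:%s (value ~ 0)", cn[i])); next
      }
      if (op %in% c("sqrt", "log", "boxcox") && !pos) {
        skipped <- c(skipped, sprintf("unary:%s:%s (non-positive values)", op, cn[i])); next
      }
      if (op == "boxcox") {
        for (lam in cfg$boxcox_lambdas) {
          cols[[length(cols) + 1L]] <- (x^lam - 1) / lam
          nms <- c(nms, sprintf("%s_boxcox%g", cn[i], lam))
          prov <- c(prov, sprintf("unary:boxcox%g:%s", lam, cn[i]))
        }
        next
      }
      v <- switch(op, inverse = 1 / x, square = x^2, sqrt = sqrt(x), log = log(x))
      cols[[length(cols) + 1L]] <- v
      nms <- c(nms, paste(cn[i], op, sep = "_"))
      prov <- c(prov, sprintf("unary:%s:%s", op, cn[i]))
    }
  }
  new_fe_block(env_ids, cols, nms, prov, skipped)
}

#' Engineer the full covariate candidate set
#'
#' Concatenates the original covariates with all pairwise arithmetic
#' combinations and all unary transforms, in a deterministic order
#' (originals, then pairwise in pair order x operation order, then unary in
#' column order x operation order). The result feeds the correlation-based
#' selection of [select_covariates()].
#'
#' @inheritParams pairwise_features
#' @return An `env_covariate_table` with the concatenated columns; provenance
#'   distinguishes original from engineered columns.
#' @export
engineer_covariates <- function(W, cfg = fe_config()) {
  stopifnot(inherits(W, "env_covariate_table"), inherits(cfg, "fe_config"))
  if (any(attr(W, "provenance") != "original")) {
    stop("non-original columns present; engineer_covariates() must not be re-applied",
         call. = FALSE)
  }
  pw <- pairwise_features(W, cfg)
  un <- unary_features(W, cfg)
  out <- cbind(unclass(W), unclass(pw), unclass(un))
  out <- env_covariate_table(out,
    provenance = c(attr(W, "provenance"), attr(pw, "provenance"), attr(un, "provenance")))
  attr(out, "skipped") <- c(attr(pw, "skipped"), attr(un, "skipped"))
  out
}
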