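#' Derived wing traits
#'
#' Secondary length is wing length minus Kipp's distance; the hand-wing
#' index is Kipp's distance divided by wing length (a dimensionless
#' dispersal-related wing-shape metric in `[0, 1]`).
#'
#' @param wing_length wing length (mm), positive.
#' @param kipps_distance Kipp's distance (mm), in `[0, wing_length]`.
#' @return data frame with `secondary_length` (mm) and `hand_wing_index`.
#' @export
derive_wing_traits <- function(wing_length, kipps_distance) {
  if (any(wing_length <= 0)) stop("wing_length must be positive")
  if (any(kipps_distance < 0)) stop("kipps_distance must be nonnegative")
  bad <- which(kipps_distance > wing_length)
  if (length(bad) > 0L) {
    stop("kipps_distance exceeds wing_length at entry ", bad[1L],
         ": inconsistent measurement")
  }
  data.frame(secondary_length = wing_length - kipps_distance,
             hand_wing_index = kipps_distance / wing_length)
}

#' Preprocess a trait table for morphospace construction
#'
#' Species with any missing trait are dropped (and reported). Traits are
#' natural-log transformed, except those named in `log_exempt` (by default
#' the hand-wing index, which is a ratio), then standardised to mean 0 and
#' sample standard deviation 1 (n - 1 denominator).
#'
#' @param table data frame with a species-id column plus numeric trait
#'   columns.
#' @param log_exempt character vector of trait names kept on the raw scale.
#' @param species_col name of the species-id column.
#' @return list with `x` (standardised matrix, species as rownames),
#'   `transform` (traits, log flags, means, SDs — everything needed to
#'   transform new species identically) and `dropped` (species removed).
#' @export
preprocess_traits <- function(table, log_exempt = "hand_wing_index",
                              species_col = "species") {
  if (!species_col %in% names(table)) {
    stop("no '", species_col, "' column in the trait table")
  }
  sp <- as.character(table[[species_col]])
  if (anyDuplicated(sp)) stop("species ids must be unique")
  traits <- setdiff(names(table), species_col)
  x <- as.matrix(table[traits])
  storage.mode(x) <- "double"
  ok <- complete.cases(x)
  dropped <- sp[!ok]
  if (length(dropped) > 0L) {
    message(length(dropped), " species dropped for missing traits: ",
            paste(head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  x <- x[ok, , drop = FALSE]
  rownames(x) <- sp[ok]
  log_flags <- setNames(!(traits %in% log_exempt), traits)
  for (tr in traits[log_flags[traits]]) {
    npos <- which(x[, tr] <= 0)
    if (length(npos) > 0L) {
      stop("nonpositive value of '", tr, "' for species ",
           rownames(x)[npos[1L]], ": cannot log-transform")
    }
    x[, tr] <- log(x[, tr])
  }
  mu <- colMeans(x)
  sdev <- apply(x, 2L, sd)
  zero <- which(sdev == 0)
  if (length(zero) > 0L) {
    stop("trait '", traits[zero[1L]], "' is constant; z-score undefined")
  }
  z <- sweep(sweep(x, 2L, mu), 2L, sdev, `/`)
  list(x = z,
       transform = list(traits = traits, log_flags = log_flags,
                        mean = mu, sd = sdev),
       dropped = dropped)
}

#' Fit a PCA morphospace
#'
#' Principal components of a standardised trait matrix, ordered by
#' decreasing variance. Loading-column signs are fixed so that the
#' largest-magnitude entry of each column is positive, making repeated
#' fits reproducible across eigensolvers. Retention is a fixed `k`
#' (default 4) or, when `var_threshold` is given, the smallest `k` whose
#' cumulative variance fraction reaches it.
#'
#' @param x standardised matrix (species x traits), e.g. from
#'   [preprocess_traits()].
#' @param k number of components to retain.
#' @param var_threshold optional cumulative variance fraction in (0, 1];
#'   overrides `k`.
#' @param transform optional transform record stored with the model so
#'   [project_scores()] can take raw trait tables.
#' @return list with `model` (class `pca_model`) and `scores` (retained
#'   score matrix, species as rownames).
#' @export
fit_pca <- function(x, k = 4L, var_threshold = NULL, transform = NULL) {
  p <- prcomp(x, center = FALSE, scale. = FALSE)
  keep <- p$sdev > 1e-12 * max(p$sdev, 1e-300)
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance component(s) dropped ",
            "(rank-deficient input)")
  }
  load <- p$rotation[, keep, drop = FALSE]
  sdev <- p$sdev[keep]
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  var_frac <- sdev^2 / sum(p$sdev^2)
  if (!is.null(var_threshold)) {
    k <- which(cumsum(var_frac) >= var_threshold)[1L]
    if (is.na(k)) k <- length(var_frac)
  }
  k <- min(as.integer(k), ncol(load))
  scores <- x %*% load
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(ncol(load)))
  model <- structure(
    list(loadings = load, var_fraction = var_frac, k = k,
         transform = transform),
    class = "pca_model"
  )
  list(model = model, scores = scores[, seq_len(k), drop = FALSE])
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA morphospace:", nrow(x$loadings), "traits,", x$k,
      "retained components\n")
  cat("variance fractions:",
      paste(sprintf("%.3f", head(x$var_fraction, x$k)), collapse = " "),
      sprintf("(cumulative %.3f)\n", sum(head(x$var_fraction, x$k))))
  invisible(x)
}

#' Fit the morphospace from a raw trait table
#'
#' Convenience wrapper: [preprocess_traits()] then [fit_pca()], storing
#' the transform in the model so external species can be projected from
#' raw measurements.
#'
#' @inheritParams preprocess_traits
#' @inheritParams fit_pca
#' @return as [fit_pca()], plus `dropped`.
#' @export
fit_morphospace <- function(table, log_exempt = "hand_wing_index",
                            species_col = "species", k = 4L,
                            var_threshold = NULL) {
  pre <- preprocess_traits(table, log_exempt, species_col)
  fit <- fit_pca(pre$x, k = k, var_threshold = var_threshold,
                 transform = pre$transform)
  c(fit, list(dropped = pre$dropped))
}

#' Project species into a fitted morphospace
#'
#' Applies the model's stored log flags, means, SDs and loadings — never
#' refits. A species with the same trait values as a training species gets
#' identical scores.
#'
#' @param model a `pca_model` fitted with a stored transform, or a bare
#'   model if `table` is already a transformed matrix.
#' @param table data frame with a species column and all model traits, or
#'   an already-transformed matrix.
#' @param species_col name of the species-id column.
#' @return score matrix (species x retained components).
#' @export
project_scores <- function(model, table, species_col = "species") {
  if (!inherits(model, "pca_model")) stop("model must be a 'pca_model'")
  if (is.matrix(table)) {
    z <- table
  } else {
    tr <- model$transform
    if (is.null(tr)) stop("model has no stored transform; pass a matrix")
    missing_tr <- setdiff(tr$traits, names(table))
    if (length(missing_tr) > 0L) {
      stop("trait column(s) missing from the table: ",
           paste(missing_tr, collapse = ", "))
    }
    x <- as.matrix(table[tr$traits])
    storage.mode(x) <- "double"
    rownames(x) <- as.character(table[[species_col]])
    for (t_ in tr$traits[tr$log_flags[tr$traits]]) {
      if (any(x[, t_] <= 0)) {
        stop("nonpositive value of '", t_, "' in projection table")
      }
      x[, t_] <- log(x[, t_])
    }
    z <- sweep(sweep(x, 2L, tr$mean), 2L, tr$sd, `/`)
  }
  if (ncol(z) != nrow(model$loadings)) {
    stop("trait dimension mismatch with the model loadings")
  }
  s <- z %*% model$loadings
  s[, seq_len(model$k), drop = FALSE]
}
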