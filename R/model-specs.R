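#' Branch-partitioned omega model specification
#'
#' Describes how the nonsynonymous/synonymous rate ratio omega is
#' partitioned over the branch classes of a \code{labeled_tree}. The named
#' presets follow the usual duplicate-gene ladder over the five classes
#' \code{pre}, \code{stem_g1}, \code{stem_g5}, \code{g1}, \code{g5}:
#' \describe{
#'   \item{M0}{one omega for every branch (1 omega parameter)}
#'   \item{M2r}{pre-duplication vs all post-duplication branches (2)}
#'   \item{M3r}{pre vs the two paralog lineages, stems included (3)}
#'   \item{M4r}{pre vs the two stems vs each crown clade (4)}
#'   \item{M5r}{all five classes free (5)}
#'   \item{Mf}{free ratios: one omega per individual branch}
#' }
#' A custom partition is given as a named character vector mapping each
#' branch class to an omega parameter name.
#'
#' @param name one of \code{"M0"}, \code{"M2r"}, \code{"M3r"}, \code{"M4r"},
#'   \code{"M5r"}, \code{"Mf"}, or \code{"custom"}.
#' @param omega_map for \code{"custom"}: named character vector,
#'   branch class -> omega parameter name.
#' @return object of class \code{branch_model_spec}.
#' @export
branch_model_spec <- function(name = c("M0", "M2r", "M3r", "M4r", "M5r",
                                       "Mf", "custom"),
                              omega_map = NULL) {
  name <- match.arg(name)
  if (name == "custom" && is.null(omega_map))
    stop("custom branch model needs an omega_map")
  structure(list(name = name, kind = "branch", omega_map = omega_map),
            class = c("branch_model_spec", "codon_model_spec"))
}

#' Site-mixture and branch-site model specification
#'
#' Site models let omega vary among codon sites via a finite mixture or a
#' discretised beta distribution; every branch shares the site's omega.
#' Branch-site models additionally allow a site class whose omega switches
#' to an elevated foreground value on designated branches.
#' \describe{
#'   \item{M0}{one omega for all sites (1 parameter)}
#'   \item{M1}{nearly neutral: a constrained class 0 < omega_0 < 1 and a
#'     neutral class omega_1 = 1; free p_0, omega_0 (2)}
#'   \item{M2}{positive selection: M1 plus a class omega_2 >= 1; free p_0,
#'     p_1, omega_0, omega_2 (4)}
#'   \item{M3}{discrete with K classes (default 3); free proportions and
#'     omegas (2K - 1)}
#'   \item{M7}{beta: omega ~ Beta(p, q) on (0, 1), discretised into
#'     \code{n_beta_categories} equal-probability classes (2)}
#'   \item{M8}{beta & omega: proportion p_0 from the beta plus an extra
#'     class with omega >= 1 (4)}
#'   \item{bsA}{branch-site model A: background classes 0 < omega_0 < 1 and
#'     omega_1 = 1; on foreground branches a fraction of each class switches
#'     to omega_2 >= 1; free p_0, p_1, omega_0, omega_2 (4)}
#'   \item{bsB}{branch-site model B: as A but omega_0 and omega_1 free and
#'     the foreground omega_2 unconstrained (5)}
#' }
#'
#' @param name model name as above.
#' @param n_classes number of discrete classes for M3 (default 3).
#' @param n_beta_categories beta discretisation count for M7/M8 (default 10,
#'   equal-probability quantile midpoints).
#' @param foreground character vector of branch classes treated as
#'   foreground (branch-site models only).
#' @return object of class \code{site_model_spec}.
#' @export
site_model_spec <- function(name = c("M0", "M1", "M2", "M3", "M7", "M8",
                                     "bsA", "bsB"),
                            n_classes = 3L, n_beta_categories = 10L,
                            foreground = NULL) {
  name <- match.arg(name)
  kind <- if (name %in% c("bsA", "bsB")) "branch_site" else "site"
  if (kind == "branch_site" && is.null(foreground))
    stop("branch-site models need foreground branch classes")
  structure(list(name = name, kind = kind, n_classes = as.integer(n_classes),
                 n_beta_categories = as.integer(n_beta_categories),
                 foreground = foreground),
            class = c("site_model_spec", "codon_model_spec"))
}

#' @export
print.codon_model_spec <- function(x, ...) {
  cat("codon model spec:", x$name, "(", x$kind, ")\n")
  invisible(x)
}

# class -> parameter-name map for the named branch-model presets
#' @noRd
preset_map <- function(class_levels, groups) {
  map <- character(0)
  for (pn in names(groups)) for (cl in groups[[pn]]) map[cl] <- pn
  missing <- setdiff(class_levels, names(map))
  if (length(missing))
    stop("branch-model preset expects classes {pre, stem_g1, stem_g5, g1, ",
         "g5}; tree has unknown class(es): ", paste(missing, collapse = ", "))
  stats::setNames(map[class_levels], class_levels)
}

# Equal-probability quantile midpoints of Beta(p, q).
#' @noRd
beta_categories <- function(p, q, n) {
  stats::qbeta((2 * seq_len(n) - 1) / (2 * n), p, q)
}

# ---------------------------------------------------------------------------
# Compilation: turn a spec + the tree's branch classes into a parameter
# layout the optimizer understands.
#
# A layout has:
#   par: data.frame(name, transform in {log, logit, log_ge1}, init, lower,
#        upper)  -- natural-scale bounds
#   resolve(params): named list of natural values -> list(
#        weights  : numeric K (site-class proportions),
#        omega_kc : K x n_class matrix of omega, columns named by class)
#   n_omega_params: the model's reported parameter count p
# ---------------------------------------------------------------------------

#' @noRd
compile_spec <- function(spec, class_levels) {
  if (inherits(spec, "branch_model_spec")) {
    map <- switch(spec$name,
      M0  = stats::setNames(rep("w", length(class_levels)), class_levels),
      M2r = preset_map(class_levels, list(w0 = "pre",
              w_post = c("stem_g1", "stem_g5", "g1", "g5"))),
      M3r = preset_map(class_levels, list(w0 = "pre",
              w1 = c("stem_g1", "g1"), w5 = c("stem_g5", "g5"))),
      M4r = preset_map(class_levels, list(w0 = "pre",
              wd = c("stem_g1", "stem_g5"), w1 = "g1", w5 = "g5")),
      M5r = preset_map(class_levels, list(w0 = "pre", wd1 = "stem_g1",
              wd5 = "stem_g5", w1 = "g1", w5 = "g5")),
      Mf  = stats::setNames(paste0("w_", class_levels), class_levels),
      custom = {
        if (!all(class_levels %in% names(spec$omega_map)))
          stop("omega_map missing class(es): ",
               paste(setdiff(class_levels, names(spec$omega_map)),
                     collapse = ", "))
        spec$omega_map[class_levels]
      })
    pars <- unique(unname(map))
    layout <- list(
      par = data.frame(name = pars, transform = "log",
                       lower = 1e-6, upper = 999, role = "omega",
                       stringsAsFactors = FALSE),
      n_omega_params = length(pars),
      K = 1L,
      resolve = function(params) {
        om <- vapply(map, function(pn) params[[pn]], numeric(1))
        list(weights = 1,
             omega_kc = matrix(om, 1, dimnames = list(NULL, class_levels)))
      })
    return(layout)
  }

  # site / branch-site models
  nc <- length(class_levels)
  fg <- class_levels %in% spec$foreground
  if (spec$kind == "branch_site" && !any(fg))
    stop("no tree branch class matches the foreground set")
  omat <- function(omegas_by_class) {
    # omegas_by_class: per site class either a scalar (all branches) or
    # c(bg =, fg =)
    m <- t(vapply(omegas_by_class, function(o) {
      if (length(o) == 1L) rep(unname(o), nc)
      else ifelse(fg, o[["fg"]], o[["bg"]])
    }, numeric(nc)))
    colnames(m) <- class_levels
    m
  }
  pd <- function(name, transform, lower, upper, role)
    data.frame(name = name, transform = transform, lower = lower,
               upper = upper, role = role, stringsAsFactors = FALSE)

  switch(spec$name,
    M0 = list(
      par = pd("w", "log", 1e-6, 999, "omega"),
      n_omega_params = 1L, K = 1L,
      resolve = function(p) list(weights = 1, omega_kc = omat(list(p$w)))),
    M1 = list(
      par = rbind(pd("p0", "logit", 1e-9, 1 - 1e-9, "prop"),
                  pd("w0", "logit", 1e-6, 1 - 1e-6, "omega")),
      n_omega_params = 2L, K = 2L,
      resolve = function(p) list(
        weights = c(p$p0, 1 - p$p0),
        omega_kc = omat(list(p$w0, 1)))),
    M2 = list(
      par = rbind(pd("p0", "logit", 1e-9, 1 - 1e-9, "prop"),
                  pd("p1", "logit", 1e-9, 1 - 1e-9, "prop"),
                  pd("w0", "logit", 1e-6, 1 - 1e-6, "omega"),
                  pd("w2", "log_ge1", 1, 999, "omega")),
      n_omega_params = 4L, K = 3L,
      resolve = function(p) {
        # p0, p1 are stick-breaking fractions: w = (p0, (1-p0)p1, rest)
        w <- c(p$p0, (1 - p$p0) * p$p1, (1 - p$p0) * (1 - p$p1))
        list(weights = w, omega_kc = omat(list(p$w0, 1, p$w2)))
      }),
    M3 = {
      K <- spec$n_classes
      nm_p <- paste0("p", seq_len(K - 1) - 1)
      nm_w <- paste0("w", seq_len(K) - 1)
      list(
        par = rbind(pd(nm_p, "logit", 1e-9, 1 - 1e-9, "prop"),
                    pd(nm_w, "log", 1e-6, 999, "omega")),
        n_omega_params = 2L * K - 1L, K = K,
        resolve = function(p) {
          fr <- vapply(nm_p, function(n) p[[n]], numeric(1))
          w <- stick_weights(fr)
          list(weights = w,
               omega_kc = omat(lapply(nm_w, function(n) p[[n]])))
        })
    },
    M7 = list(
      par = rbind(pd("p", "log", 0.005, 99, "beta"), pd("q", "log", 0.005, 99, "beta")),
      n_omega_params = 2L, K = spec$n_beta_categories,
      resolve = function(p) {
        om <- beta_categories(p$p, p$q, spec$n_beta_categories)
        list(weights = rep(1 / spec$n_beta_categories,
                           spec$n_beta_categories),
             omega_kc = omat(as.list(om)))
      }),
    M8 = list(
      par = rbind(pd("p0", "logit", 1e-9, 1 - 1e-9, "prop"),
                  pd("p", "log", 0.005, 99, "beta"), pd("q", "log", 0.005, 99, "beta"),
                  pd("w", "log_ge1", 1, 999, "omega")),
      n_omega_params = 4L, K = spec$n_beta_categories + 1L,
      resolve = function(p) {
        nb <- spec$n_beta_categories
        om <- beta_categories(p$p, p$q, nb)
        list(weights = c(rep(p$p0 / nb, nb), 1 - p$p0),
             omega_kc = omat(c(as.list(om), list(p$w))))
      }),
    bsA = list(
      par = rbind(pd("p0", "logit", 1e-9, 1 - 1e-9, "prop"),
                  pd("p1", "logit", 1e-9, 1 - 1e-9, "prop"),
                  pd("w0", "logit", 1e-6, 1 - 1e-6, "omega"),
                  pd("w2", "log_ge1", 1, 999, "omega")),
      n_omega_params = 4L, K = 4L,
      resolve = function(p) list(
        weights = bs_weights(p$p0, p$p1),
        omega_kc = omat(list(p$w0, 1,
                             c(bg = p$w0, fg = p$w2),
                             c(bg = 1, fg = p$w2)))),
      flag_classes = 3:4),
    bsB = list(
      par = rbind(pd("p0", "logit", 1e-9, 1 - 1e-9, "prop"),
                  pd("p1", "logit", 1e-9, 1 - 1e-9, "prop"),
                  pd("w0", "log", 1e-6, 999, "omega"),
                  pd("w1", "log", 1e-6, 999, "omega"),
                  pd("w2", "log", 1e-6, 999, "omega")),
      n_omega_params = 5L, K = 4L,
      resolve = function(p) list(
        weights = bs_weights(p$p0, p$p1),
        omega_kc = omat(list(p$w0, p$w1,
                             c(bg = p$w0, fg = p$w2),
                             c(bg = p$w1, fg = p$w2)))),
      flag_classes = 3:4),
    stop("unsupported site model: ", spec$name))
}

# stick-breaking fractions -> simplex weights (length(fr) + 1 classes)
#' @noRd
stick_weights <- function(fr) {
  K <- length(fr) + 1L
  w <- numeric(K)
  rest <- 1
  for (k in seq_along(fr)) {
    w[k] <- rest * fr[k]
    rest <- rest - w[k]
  }
  w[K] <- rest
  w
}

# Branch-site class proportions: stick-breaking masses (q0, q1, q2) over
# (class0, class1, switching), with the switching mass split between the
# two switching classes in proportion q0 : q1.
#' @noRd
bs_weights <- function(p0, p1) {
  w <- stick_weights(c(p0, p1))  # (q0, q1, q2)
  split <- if (w[1] + w[2] > 0) w[1] / (w[1] + w[2]) else 0.5
  c(w[1], w[2], w[3] * split, w[3] * (1 - split))
}
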