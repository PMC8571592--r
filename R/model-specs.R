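#' Build a structured Mk model specification
#'
#' Constructs the parameter-sharing template for one of the six transition
#' models used for the three-state substrate-preference character. The
#' observed states are always ordered (arboreal, semi-arboreal, nonarboreal);
#' hidden-rate-class models expand the state space to (state, class) pairs,
#' blocked by class: (A1, S1, N1, A2, S2, N2, ...).
#'
#' Models:
#' \describe{
#'   \item{two_rate}{all six transitions allowed; the four transitions to or
#'     from semi-arboreal share one rate, the two direct arboreal/nonarboreal
#'     transitions share a second (k = 2).}
#'   \item{four_rate}{ordered model: arboreal <-> semi-arboreal and
#'     semi-arboreal <-> nonarboreal each get separate forward and reverse
#'     rates; direct arboreal <-> nonarboreal transitions are structural
#'     zeros (k = 4).}
#'   \item{ard}{all rates different: six free rates (k = 6).}
#'   \item{hmm_ard_plus_four_rate_2class}{two hidden rate classes, one with
#'     the ARD template and one with the four-rate template, linked by a
#'     single symmetric class-switch rate (k = 11).}
#'   \item{hmm_ard_2class}{two ARD classes plus the switch rate (k = 13).}
#'   \item{hmm_ard_3class}{three ARD classes plus the switch rate (k = 19).}
#' }
#'
#' Class switching is modeled as a single shared rate, symmetric, connecting
#' the same observed state across classes only (observed state and hidden
#' class never change in the same instant).
#'
#' @param name one of `"two_rate"`, `"four_rate"`, `"ard"`,
#'   `"hmm_ard_plus_four_rate_2class"`, `"hmm_ard_2class"`, `"hmm_ard_3class"`.
#' @return an object of class `"mk_model_spec"`: a list with `name`,
#'   `n_class`, `n_expanded`, `states` (expanded-state labels), `index`
#'   (integer matrix; 0 = structural zero, equal positive entries share a
#'   parameter) and `k` (free-parameter count).
#' @examples
#' spec <- build_model_spec("four_rate")
#' spec$index   # note the structural zeros at (A,N) and (N,A)
#' @export
build_model_spec <- function(name) {
  templates <- list(
    two_rate  = matrix(c(0, 1, 2,
                         1, 0, 1,
                         2, 1, 0), 3, 3, byrow = TRUE),
    four_rate = matrix(c(0, 1, 0,
                         2, 0, 3,
                         0, 4, 0), 3, 3, byrow = TRUE),
    ard       = matrix(c(0, 1, 2,
                         3, 0, 4,
                         5, 6, 0), 3, 3, byrow = TRUE)
  )
  hmm_defs <- list(
    hmm_ard_plus_four_rate_2class = list("ard", "four_rate"),
    hmm_ard_2class                = list("ard", "ard"),
    hmm_ard_3class                = list("ard", "ard", "ard")
  )
  valid <- c(names(templates), names(hmm_defs))
  if (!name %in% valid)
    stop("unknown model name '", name, "'; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)

  if (name %in% names(templates)) {
    blocks <- list(templates[[name]])
  } else {
    blocks <- lapply(hmm_defs[[name]], function(b) templates[[b]])
  }
  c_cls <- length(blocks)
  m <- 3L * c_cls
  index <- matrix(0L, m, m)
  offset <- 0L
  for (cl in seq_len(c_cls)) {
    blk <- blocks[[cl]]
    shifted <- blk
    shifted[blk > 0] <- blk[blk > 0] + offset
    rows <- (cl - 1L) * 3L + 1:3
    index[rows, rows] <- shifted
    offset <- offset + max(blk)
  }
  if (c_cls > 1L) {
    switch_idx <- offset + 1L
    for (cl1 in seq_len(c_cls - 1L)) for (cl2 in (cl1 + 1L):c_cls) {
      for (s in 1:3) {
        i <- (cl1 - 1L) * 3L + s
        j <- (cl2 - 1L) * 3L + s
        index[i, j] <- switch_idx
        index[j, i] <- switch_idx
      }
    }
    k <- switch_idx
  } else {
    k <- offset
  }
  st <- if (c_cls == 1L) arb_states()
        else as.vector(t(outer(seq_len(c_cls), arb_states(),
                               function(cl, s) paste0(s, "_c", cl))))
  dimnames(index) <- list(st, st)
  structure(list(name = name, n_class = c_cls, n_expanded = m,
                 states = st, index = index, k = as.integer(k)),
            class = "mk_model_spec")
}

#' @export
print.mk_model_spec <- function(x, ...) {
  cat("Mk model spec '", x$name, "': ", x$n_expanded, " expanded states (",
      x$n_class, " rate class", if (x$n_class > 1) "es", "), k = ", x$k,
      " free parameters\n", sep = "")
  print(x$index)
  invisible(x)
}

#' Instantiate a rate matrix from a model spec
#'
#' Fills the off-diagonal entries of the CTMC generator by parameter-index
#' lookup and sets each diagonal to minus the row sum, so rows sum to zero.
#' Structural zeros of the spec are exactly 0.
#'
#' @param spec an `"mk_model_spec"`.
#' @param params numeric vector of `spec$k` non-negative rates (1/Myr).
#' @return square rate matrix over the expanded state space.
#' @export
assemble_q <- function(spec, params) {
  stopifnot(inherits(spec, "mk_model_spec"))
  if (length(params) != spec$k)
    stop("expected ", spec$k, " rates, got ", length(params), call. = FALSE)
  if (any(!is.finite(params)) || any(params < 0))
    stop("rates must be finite and >= 0", call. = FALSE)
  Q <- matrix(0, spec$n_expanded, spec$n_expanded,
              dimnames = dimnames(spec$index))
  nz <- spec$index > 0
  Q[nz] <- params[spec$index[nz]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Akaike information criterion
#'
#' @param logL maximized log-likelihood.
#' @param k number of free parameters (>= 1).
#' @return `2 * k - 2 * logL`.
#' @export
aic_score <- function(logL, k) {
  stopifnot(k >= 1)
  2 * k - 2 * logL
}

#' Small-sample corrected AIC
#'
#' Optional alternative to [aic_score()]; not used by default.
#'
#' @param logL maximized log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (number of tips).
#' @return AICc value.
#' @export
aicc_score <- function(logL, k, n) {
  stopifnot(k >= 1, n > k + 1)
  aic_score(logL, k) + 2 * k * (k + 1) / (n - k - 1)
}
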