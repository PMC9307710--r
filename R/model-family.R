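#' Specify a model in the factorial SDT family
#'
#' The model family crosses four hypotheses about response criteria with
#' five about discriminability:
#' \describe{
#'   \item{tau1}{one criterion, fixed across positions and sequences}
#'   \item{tau2}{criteria free across positions, unaffected by the target}
#'   \item{tau3}{one baseline criterion plus a target-rejection shift
#'     `delta * exp(lambda * (h - i))`}
#'   \item{tau4}{position-varying criteria plus the target-rejection shift}
#'   \item{null}{fixed latent-strength distributions}
#'   \item{mu1 / mu2}{target and lure means shift symmetrically about the
#'     origin by a factor `alpha`, once after position 1 (`mu1`) or freely
#'     per position (`mu2`)}
#'   \item{sigma1 / sigma2}{both variances scale by a factor `xi`, once
#'     after position 1 (`sigma1`) or freely per position (`sigma2`)}
#' }
#' Optional extensions add ordered confidence criteria (increments `kappa`
#' with post-rejection modulation `omega`, `eta`, `gamma`) and a
#' serious/unserious mixture (`pi`, `zeta`). Named restrictions remove or
#' reparameterise blocks:
#' `fixed_tau0` (criteria equal across positions), `monotone_increasing_tau0`
#' / `monotone_decreasing_tau0` (criteria ordered across positions, built
#' from cumulative signed increments), `lambda_zero` (constant shift at all
#' lags), `equal_variance` (`sigma2_T = sigma2_L = 1`),
#' `omega_eta_gamma_fixed` (confidence increments rigid after a rejection)
#' and `shared_kappa_across_positions`.
#'
#' @param criterion One of `"tau1"`, `"tau2"`, `"tau3"`, `"tau4"`.
#' @param discriminability One of `"null"`, `"mu1"`, `"sigma1"`, `"mu2"`,
#'   `"sigma2"`.
#' @param confidence Logical; add the confidence-rating extension.
#' @param mixture Logical; add the serious/unserious mixture.
#' @param restrictions Character vector of restriction names (see above).
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("tau4")                       # the 10-parameter binary model
#' model_spec("tau4", restrictions = "lambda_zero")
#' @export
model_spec <- function(criterion = c("tau1", "tau2", "tau3", "tau4"),
                       discriminability = c("null", "mu1", "sigma1", "mu2", "sigma2"),
                       confidence = FALSE, mixture = FALSE,
                       restrictions = character()) {
  criterion <- match.arg(criterion)
  discriminability <- match.arg(discriminability)
  known <- c("fixed_tau0", "monotone_increasing_tau0", "monotone_decreasing_tau0",
             "lambda_zero", "equal_variance", "omega_eta_gamma_fixed",
             "shared_kappa_across_positions")
  bad <- setdiff(restrictions, known)
  if (length(bad)) stop("unknown restriction(s): ", paste(bad, collapse = ", "))
  restrictions <- unique(restrictions)
  per_position <- criterion %in% c("tau2", "tau4")
  if (any(c("monotone_increasing_tau0", "monotone_decreasing_tau0",
            "fixed_tau0") %in% restrictions) && !per_position)
    stop("criterion-ordering restrictions require per-position criteria (tau2 or tau4)")
  if (all(c("monotone_increasing_tau0", "monotone_decreasing_tau0") %in% restrictions))
    stop("cannot impose increasing and decreasing criteria simultaneously")
  if ("fixed_tau0" %in% restrictions &&
      any(c("monotone_increasing_tau0", "monotone_decreasing_tau0") %in% restrictions))
    stop("'fixed_tau0' conflicts with monotone criterion restrictions")
  if ("lambda_zero" %in% restrictions && !criterion %in% c("tau3", "tau4"))
    stop("'lambda_zero' requires a target-rejection kernel (tau3 or tau4)")
  if (any(c("omega_eta_gamma_fixed", "shared_kappa_across_positions") %in% restrictions)
      && !confidence)
    stop("confidence restrictions require confidence = TRUE")
  structure(list(criterion = criterion, discriminability = discriminability,
                 confidence = confidence, mixture = mixture,
                 restrictions = restrictions),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(format_model_spec(x), "\n")
  invisible(x)
}

#' Compact model-spec strings
#'
#' `format_model_spec()` renders a spec as e.g.
#' `"tau4+mu1[confidence][mixture][restr:lambda_zero]"`;
#' `parse_model_spec()` inverts it.
#'
#' @param spec A [model_spec()].
#' @return A character scalar, or a `model_spec` for `parse_model_spec()`.
#' @export
format_model_spec <- function(spec) {
  s <- paste0(spec$criterion, "+", spec$discriminability)
  if (spec$confidence) s <- paste0(s, "[confidence]")
  if (spec$mixture) s <- paste0(s, "[mixture]")
  if (length(spec$restrictions))
    s <- paste0(s, "[restr:", paste(spec$restrictions, collapse = ","), "]")
  s
}

#' @rdname format_model_spec
#' @param string A string produced by `format_model_spec()`.
#' @export
parse_model_spec <- function(string) {
  main <- sub("\\[.*$", "", string)
  parts <- strsplit(main, "+", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) parts <- c(parts, "null")
  if (length(parts) != 2L) stop("cannot parse model string: ", string)
  tags <- regmatches(string, gregexpr("\\[[^]]*\\]", string))[[1L]]
  restr <- character()
  conf <- any(tags == "[confidence]")
  mixt <- any(tags == "[mixture]")
  rt <- grep("^\\[restr:", tags, value = TRUE)
  if (length(rt))
    restr <- strsplit(sub("^\\[restr:(.*)\\]$", "\\1", rt[1L]), ",")[[1L]]
  model_spec(parts[1L], parts[2L], confidence = conf, mixture = mixt,
             restrictions = restr)
}

# ---------------------------------------------------------------------------
# Parameter layout: ordered free parameters with transforms between the
# unbounded optimisation space and the natural sdt_params space.

#' Build the free-parameter layout of a model
#'
#' Enumerates the free parameters of a model (in canonical order) together
#' with the transforms that map an unbounded free vector to a valid
#' [sdt_params()] set: variances, decay rates and increments live on the log
#' scale, the mixture weight on the logistic scale, and ordered criteria are
#' built from cumulative signed log-increments. Anchored quantities
#' (`alpha[1] = xi[1] = 1`, the lure distribution) are never free.
#'
#' @param spec A [model_spec()].
#' @param design A [lineup_design()]; confidence models require `K >= 2`.
#' @return An object of class `model_layout` with elements `spec`, `design`,
#'   `par_names` and `n_free`.
#' @seealso [to_natural()], [from_natural()], [parameter_count()]
#' @export
build_model <- function(spec, design) {
  stopifnot(inherits(spec, "model_spec"), inherits(design, "lineup_design"))
  if (spec$confidence && design$K < 2L)
    stop("confidence models require a design with K >= 2")
  if (!spec$confidence && design$K > 1L)
    stop("a K > 1 design requires confidence = TRUE")
  I <- design$I; K <- design$K
  r <- spec$restrictions
  nm <- "mu_T"
  if (!"equal_variance" %in% r) nm <- c(nm, "log_sigma2_T")
  per_position <- spec$criterion %in% c("tau2", "tau4") && !"fixed_tau0" %in% r
  if (!per_position) {
    nm <- c(nm, "tau0")
  } else if ("monotone_increasing_tau0" %in% r || "monotone_decreasing_tau0" %in% r) {
    nm <- c(nm, "tau0_1", paste0("log_dtau_", 2:I))
  } else {
    nm <- c(nm, paste0("tau0_", seq_len(I)))
  }
  if (spec$criterion %in% c("tau3", "tau4")) {
    nm <- c(nm, "delta")
    if (!"lambda_zero" %in% r) nm <- c(nm, "log_lambda")
  }
  nm <- c(nm, switch(spec$discriminability,
                     null = character(),
                     mu1 = "log_alpha",
                     sigma1 = "log_xi",
                     mu2 = paste0("log_alpha_", 2:I),
                     sigma2 = paste0("log_xi_", 2:I)))
  if (spec$confidence) {
    if ("shared_kappa_across_positions" %in% r) {
      nm <- c(nm, paste0("log_kappa_", seq_len(K - 1L)))
    } else {
      nm <- c(nm, paste0("log_kappa_",
                         rep(seq_len(K - 1L), I), "_", rep(seq_len(I), each = K - 1L)))
    }
    if (!"omega_eta_gamma_fixed" %in% r) nm <- c(nm, "log_omega", "eta", "gamma")
  }
  if (spec$mixture) {
    nm <- c(nm, "logit_pi")
    if (spec$confidence) nm <- c(nm, "log_zeta")
  }
  structure(list(spec = spec, design = design, par_names = nm,
                 n_free = length(nm)),
            class = "model_layout")
}

#' @export
print.model_layout <- function(x, ...) {
  cat(format_model_spec(x$spec), "on I =", x$design$I, ", K =", x$design$K,
      ":", x$n_free, "free parameters\n")
  cat(" ", paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

#' Map a free vector to natural parameters and back
#'
#' `to_natural()` converts an unbounded free vector into a valid
#' [sdt_params()] set (any finite vector yields admissible parameters);
#' `from_natural()` inverts the map. The round trip is the identity.
#'
#' @param layout A [build_model()] layout.
#' @param free Numeric vector of length `layout$n_free`.
#' @return An [sdt_params()] object, or a free vector for `from_natural()`.
#' @export
to_natural <- function(layout, free) {
  stopifnot(inherits(layout, "model_layout"))
  if (length(free) != layout$n_free)
    stop(sprintf("free vector has length %d, layout expects %d",
                 length(free), layout$n_free))
  spec <- layout$spec; I <- layout$design$I; K <- layout$design$K
  r <- spec$restrictions
  v <- stats::setNames(free, layout$par_names)
  take <- function(pat) v[grep(pat, names(v))]
  mu_T <- v[["mu_T"]]
  sigma2_T <- if ("equal_variance" %in% r) 1 else exp(v[["log_sigma2_T"]])
  per_position <- spec$criterion %in% c("tau2", "tau4") && !"fixed_tau0" %in% r
  if (!per_position) {
    tau0 <- rep(v[["tau0"]], I)
  } else if ("monotone_increasing_tau0" %in% r) {
    tau0 <- cumsum(c(v[["tau0_1"]], exp(take("^log_dtau_"))))
  } else if ("monotone_decreasing_tau0" %in% r) {
    tau0 <- cumsum(c(v[["tau0_1"]], -exp(take("^log_dtau_"))))
  } else {
    tau0 <- unname(take("^tau0_"))
  }
  delta <- 0; lambda <- 0
  if (spec$criterion %in% c("tau3", "tau4")) {
    delta <- v[["delta"]]
    if (!"lambda_zero" %in% r) lambda <- exp(v[["log_lambda"]])
  }
  alpha <- 1; xi <- 1
  if (spec$discriminability == "mu1") alpha <- exp(v[["log_alpha"]])
  if (spec$discriminability == "sigma1") xi <- exp(v[["log_xi"]])
  if (spec$discriminability == "mu2") alpha <- c(1, exp(unname(take("^log_alpha_"))))
  if (spec$discriminability == "sigma2") xi <- c(1, exp(unname(take("^log_xi_"))))
  kappa <- NULL; omega <- 1; eta <- 0; gamma <- 0
  if (spec$confidence) {
    kv <- exp(unname(take("^log_kappa_")))
    kappa <- if ("shared_kappa_across_positions" %in% r)
      matrix(kv, nrow = K - 1L, ncol = I) else matrix(kv, nrow = K - 1L, ncol = I)
    if (!"omega_eta_gamma_fixed" %in% r) {
      omega <- exp(v[["log_omega"]]); eta <- v[["eta"]]; gamma <- v[["gamma"]]
    }
  }
  pi_serious <- 1; zeta <- 1
  if (spec$mixture) {
    pi_serious <- stats::plogis(v[["logit_pi"]])
    if (spec$confidence) zeta <- exp(v[["log_zeta"]])
  }
  sdt_params(mu_T = mu_T, sigma2_T = sigma2_T, tau0 = tau0, delta = delta,
             lambda = lambda, alpha = alpha, xi = xi, kappa = kappa,
             omega = omega, eta = eta, gamma = gamma,
             pi_serious = pi_serious, zeta = zeta, I = I)
}

#' @rdname to_natural
#' @param params An [sdt_params()] set consistent with the layout (e.g.
#'   monotone layouts need strictly ordered criteria).
#' @export
from_natural <- function(layout, params) {
  stopifnot(inherits(layout, "model_layout"), inherits(params, "sdt_params"))
  spec <- layout$spec; I <- layout$design$I; K <- layout$design$K
  r <- spec$restrictions
  out <- c(mu_T = params$mu_T)
  if (!"equal_variance" %in% r) out <- c(out, log_sigma2_T = log(params$sigma2_T))
  per_position <- spec$criterion %in% c("tau2", "tau4") && !"fixed_tau0" %in% r
  if (!per_position) {
    out <- c(out, tau0 = params$tau0[1L])
  } else if ("monotone_increasing_tau0" %in% r) {
    d <- diff(params$tau0)
    if (any(d <= 0)) stop("criteria are not strictly increasing")
    out <- c(out, tau0_1 = params$tau0[1L],
             stats::setNames(log(d), paste0("log_dtau_", 2:I)))
  } else if ("monotone_decreasing_tau0" %in% r) {
    d <- -diff(params$tau0)
    if (any(d <= 0)) stop("criteria are not strictly decreasing")
    out <- c(out, tau0_1 = params$tau0[1L],
             stats::setNames(log(d), paste0("log_dtau_", 2:I)))
  } else {
    out <- c(out, stats::setNames(params$tau0, paste0("tau0_", seq_len(I))))
  }
  if (spec$criterion %in% c("tau3", "tau4")) {
    out <- c(out, delta = params$delta)
    if (!"lambda_zero" %in% r) out <- c(out, log_lambda = log(params$lambda))
  }
  out <- c(out, switch(spec$discriminability,
    null = NULL,
    mu1 = c(log_alpha = log(params$alpha[2L])),
    sigma1 = c(log_xi = log(params$xi[2L])),
    mu2 = stats::setNames(log(params$alpha[2:I]), paste0("log_alpha_", 2:I)),
    sigma2 = stats::setNames(log(params$xi[2:I]), paste0("log_xi_", 2:I))))
  if (spec$confidence) {
    if ("shared_kappa_across_positions" %in% r) {
      out <- c(out, stats::setNames(log(params$kappa[, 1L]),
                                    paste0("log_kappa_", seq_len(K - 1L))))
    } else {
      out <- c(out, stats::setNames(log(as.vector(params$kappa)),
        paste0("log_kappa_", rep(seq_len(K - 1L), I), "_",
               rep(seq_len(I), each = K - 1L))))
    }
    if (!"omega_eta_gamma_fixed" %in% r)
      out <- c(out, log_omega = log(params$omega), eta = params$eta,
               gamma = params$gamma)
  }
  if (spec$mixture) {
    out <- c(out, logit_pi = stats::qlogis(params$pi_serious))
    if (spec$confidence) out <- c(out, log_zeta = log(params$zeta))
  }
  unname(out[layout$par_names])
}

#' Number of free parameters of a model
#'
#' @inheritParams build_model
#' @param published_count_mode Logical. The published model-comparison table
#'   lists the K = 4 confidence models with one parameter fewer than the
#'   layout implied by the stated extension formula `6 * (K - 1) + 3` over
#'   the binary base; the full layout (default) is what this package
#'   estimates. Setting `published_count_mode = TRUE` reports the published
#'   count (one fewer for confidence models) for side-by-side comparison of
#'   AIC/BIC arithmetic.
#' @return Integer count of free parameters.
#' @examples
#' parameter_count(model_spec("tau1"), lineup_design(6))  # 3
#' parameter_count(model_spec("tau4"), lineup_design(6))  # 10
#' @export
parameter_count <- function(spec, design, published_count_mode = FALSE) {
  n <- build_model(spec, design)$n_free
  if (published_count_mode && spec$confidence) n <- n - 1L
  n
}

# Rough nesting check used by lr_test(): restricted must be reachable from
# full by removing freedom. Covers the documented pairs (variant orderings
# and added restrictions); exotic pairs can bypass with check_nesting=FALSE.
is_nested_spec <- function(restricted, full) {
  crit_rank <- c(tau1 = 1L, tau2 = 2L, tau3 = 2L, tau4 = 3L)
  disc_rank <- c(null = 1L, mu1 = 2L, sigma1 = 2L, mu2 = 3L, sigma2 = 3L)
  crit_ok <- restricted$criterion == full$criterion ||
    crit_rank[[restricted$criterion]] < crit_rank[[full$criterion]] &&
    !(restricted$criterion == "tau2" && full$criterion == "tau3") &&
    !(restricted$criterion == "tau3" && full$criterion == "tau2")
  disc_ok <- restricted$discriminability == full$discriminability ||
    disc_rank[[restricted$discriminability]] < disc_rank[[full$discriminability]] &&
    substr(restricted$discriminability, 1, 2) ==
      substr(paste0(full$discriminability, "xx"), 1, 2) ||
    restricted$discriminability == "null"
  ext_ok <- restricted$confidence == full$confidence &&
    (!restricted$mixture || full$mixture)
  restr_ok <- all(full$restrictions %in% restricted$restrictions) ||
    restricted$criterion != full$criterion
  isTRUE(crit_ok) && isTRUE(disc_ok) && ext_ok && restr_ok
}
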