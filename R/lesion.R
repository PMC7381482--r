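# Damage operators. All five operators exempt bias inputs from damage and
# are exactly reproducible from their LesionRecord (kind, severity, seed,
# target): re-applying a record to the intact network recreates the damaged
# network bit-for-bit.

trainable_matrices <- function(net) {
  if (inherits(net, "hub_net")) {
    if (net$feedforward) c("W_vh", "W_hv") else c("W_vh", "W_hh", "W_hv")
  } else if (inherits(net, "srn_net")) {
    c("W_ih", "W_ch", "W_ho")
  } else {
    stop("unsupported network class: ", paste(class(net), collapse = "/"))
  }
}

recurrent_matrix <- function(net) {
  if (inherits(net, "hub_net")) "W_hh" else "W_ch"
}

resolve_target <- function(net, target) {
  all <- trainable_matrices(net)
  if (identical(target, "all")) return(all)
  if (identical(target, "recurrent")) return(recurrent_matrix(net))
  bad <- setdiff(target, all)
  if (length(bad)) stop("unknown lesion target matrices: ", paste(bad, collapse = ", "))
  target
}

new_record <- function(kind, severity, seed, target) {
  structure(list(kind = kind, severity = severity,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 target = target),
            class = "lesion_record")
}

#' @export
print.lesion_record <- function(x, ...) {
  cat(sprintf("lesion_record: %s (severity %g, seed %s, target %s)\n",
              x$kind, x$severity, x$seed, paste(x$target, collapse = "+")))
  invisible(x)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  expr
}

#' Sever connections
#'
#' Each targeted non-bias weight is independently set to zero with
#' probability \code{q} (multiplication by a Bernoulli(1 - q) variable).
#'
#' @param net A \code{hub_net} or \code{srn_net}.
#' @param q Severing probability in [0, 1].
#' @param seed Integer seed for the Bernoulli draw.
#' @param target "all" (default: every trainable weight matrix, pooled into
#'   a single draw), "recurrent", or a character vector of matrix names.
#' @return The damaged network, with the replayable \code{lesion_record}
#'   stored in \code{$lesion_record}.
#' @export
sever <- function(net, q, seed, target = "all") {
  if (!is.numeric(q) || q < 0 || q > 1) stop("q must be in [0, 1]")
  mats <- resolve_target(net, target)
  sizes <- vapply(mats, function(m) length(net[[m]]), integer(1))
  keep <- with_seed(seed, runif(sum(sizes)) >= q)
  off <- 0L
  for (m in mats) {
    k <- keep[off + seq_len(sizes[[m]])]
    net[[m]][!k] <- 0
    off <- off + sizes[[m]]
  }
  net$lesion_record <- new_record("sever", q, seed, target)
  net
}

#' Perturb weights with uniform noise
#'
#' Independent additive noise drawn from \code{U(-r, +r)} on every targeted
#' non-bias weight.
#'
#' @inheritParams sever
#' @param r Half-range of the uniform noise (> 0).
#' @return The damaged network with its \code{lesion_record}.
#' @export
perturb_weights <- function(net, r, seed, target = "all") {
  if (!is.numeric(r) || r <= 0) stop("r must be > 0")
  mats <- resolve_target(net, target)
  sizes <- vapply(mats, function(m) length(net[[m]]), integer(1))
  noise <- with_seed(seed, runif(sum(sizes), -r, r))
  off <- 0L
  for (m in mats) {
    net[[m]] <- net[[m]] + noise[off + seq_len(sizes[[m]])]
    off <- off + sizes[[m]]
  }
  net$lesion_record <- new_record("perturb_weights", r, seed, target)
  net
}

#' Ablate hidden/context units
#'
#' Each hidden (hub) or context (SRN) unit is independently selected with
#' probability \code{p}; all outgoing connections from selected units are
#' set to zero (for the hub: the unit's rows of the hidden-to-hidden and
#' hidden-to-visible matrices; for the SRN: the unit's row of the
#' context-to-hidden matrix).  Incoming weights are retained.
#'
#' @inheritParams sever
#' @param p Ablation probability in [0, 1].
#' @return The damaged network with its \code{lesion_record}.
#' @export
ablate_units <- function(net, p, seed) {
  if (!is.numeric(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  if (inherits(net, "hub_net")) {
    if (net$feedforward) {
      n_hid <- ncol(net$W_vh)
      gone <- with_seed(seed, runif(n_hid) < p)
      net$W_hv[gone, ] <- 0
    } else {
      n_hid <- ncol(net$W_vh)
      gone <- with_seed(seed, runif(n_hid) < p)
      net$W_hh[gone, ] <- 0
      net$W_hv[gone, ] <- 0
    }
  } else if (inherits(net, "srn_net")) {
    n_ctx <- nrow(net$W_ch)
    gone <- with_seed(seed, runif(n_ctx) < p)
    net$W_ch[gone, ] <- 0
  } else {
    stop("unsupported network class")
  }
  net$lesion_record <- new_record("ablate_units", p, seed, "hidden_outgoing")
  net
}

#' Scale weights
#'
#' Deterministically multiplies every targeted non-bias weight by the
#' factor \code{s} (no seed needed; equivalent to reducing the activation
#' function's gain).
#'
#' @inheritParams sever
#' @param s Scaling factor in (0, 1].
#' @return The damaged network with its \code{lesion_record}.
#' @export
scale_weights <- function(net, s, target = "all") {
  if (!is.numeric(s) || s <= 0 || s > 1) stop("s must be in (0, 1]")
  mats <- resolve_target(net, target)
  for (m in mats) net[[m]] <- net[[m]] * s
  net$lesion_record <- new_record("scale_weights", s, NULL, target)
  net
}

#' Activation-noise injector
#'
#' Builds a per-step noise injector for sequential runs: at every
#' processing step, independent zero-mean Gaussian noise with standard
#' deviation \code{sigma} is added to the context (previous hidden)
#' activations.  Weights are untouched.  Passing the injector to
#' \code{\link{run_episode}} applies it; \code{sigma = 0} reproduces intact
#' runs exactly.
#'
#' @param sigma Noise standard deviation (>= 0).
#' @return A function-free spec of class \code{activation_noise} with
#'   element \code{sigma}.
#' @export
activation_noise <- function(sigma) {
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  structure(list(sigma = sigma), class = "activation_noise")
}

#' Replay a lesion record
#'
#' Applies the recorded operator, severity, seed and target to a network;
#' replaying the record of a damaged network on the intact original
#' reproduces the damaged network exactly.
#'
#' @param net The intact network.
#' @param record A \code{lesion_record}.
#' @return The damaged network.
#' @export
apply_lesion <- function(net, record) {
  stopifnot(inherits(record, "lesion_record"))
  switch(record$kind,
    sever = sever(net, record$severity, record$seed, record$target),
    perturb_weights = perturb_weights(net, record$severity, record$seed, record$target),
    ablate_units = ablate_units(net, record$severity, record$seed),
    scale_weights = scale_weights(net, record$severity, record$target),
    stop("unknown lesion kind: ", record$kind)
  )
}

# Dispatch a (kind, severity) pair, deriving the seed; used by the damage
# grids. Severity-0 stochastic lesions are identity operations.
lesion_by_kind <- function(net, kind, severity, seed, target = "all") {
  switch(kind,
    sever = sever(net, severity, seed, target = target),
    perturb = ,
    perturb_weights = perturb_weights(net, severity, seed, target = target),
    ablate = ,
    ablate_units = ablate_units(net, severity, seed),
    scale = ,
    scale_weights = scale_weights(net, severity, target = target),
    stop("unknown damage kind: ", kind)
  )
}
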