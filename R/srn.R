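# Simple recurrent (Elman) network for sequential action selection:
# input = featural encoding of fixated + held objects, context = previous
# hidden state, output = softmax over the 17 actions, argmax selection.

#' Configuration for the action-selection SRN
#'
#' @param n_hidden Hidden/context width (default 50).
#' @param epochs Training epochs (default 20000); each epoch presents the
#'   six whole sequences (BPTT over the full sequence) and every one-step
#'   background item.
#' @param learning_rate,momentum Online update parameters (defaults 0.01
#'   and 0.9, chosen to reach exact sequence reproduction within the
#'   default epoch budget).
#' @param init_weight_scale Uniform initial-weight half-range (default 0.3).
#' @param background_weight Gradient weight of the one-step background
#'   items relative to sequence steps (default 0.2): affordance knowledge
#'   is rehearsed every epoch but must not swamp the sequential structure.
#' @param train_noise_sd SD of Gaussian noise added to the context copy
#'   during training (default 0.02).  Training with slightly jittered
#'   context makes the learned sequence trajectories attracting, so a
#'   damaged network is recaptured by a valid subtask path instead of
#'   wandering; intact argmax behaviour is unaffected.
#' @param context_init Context activation at sequence start (default 0.5).
#' @param max_run_steps Episode cap for free-running generation (default
#'   60, comfortably above the longest 37-step sequence).
#' @return A list of class \code{srn_config}.
#' @export
srn_config <- function(n_hidden = 50L, epochs = 20000L,
                       learning_rate = 0.01, momentum = 0.9,
                       init_weight_scale = 0.3, context_init = 0.5,
                       background_weight = 0.2, train_noise_sd = 0.02,
                       max_run_steps = 60L) {
  if (n_hidden < 1L) stop("n_hidden must be positive")
  structure(list(
    n_input = 2L * N_OBJ_FEAT, n_hidden = as.integer(n_hidden),
    n_output = length(ACTIONS), epochs = as.integer(epochs),
    learning_rate = learning_rate, momentum = momentum,
    init_weight_scale = init_weight_scale, context_init = context_init,
    background_weight = background_weight, train_noise_sd = train_noise_sd,
    max_run_steps = as.integer(max_run_steps)
  ), class = "srn_config")
}

init_srn <- function(config = srn_config(), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  s <- config$init_weight_scale
  ni <- config$n_input; nh <- config$n_hidden; no <- config$n_output
  structure(list(
    W_ih = matrix(runif(ni * nh, -s, s), ni, nh),
    W_ch = matrix(runif(nh * nh, -s, s), nh, nh),
    W_ho = matrix(runif(nh * no, -s, s), nh, no),
    b_h = runif(nh, -s, s), b_o = runif(no, -s, s),
    config = config, trained = FALSE, seed = as.integer(seed)
  ), class = "srn_net")
}

# teacher trajectory -> per-step input encodings for one sequence
sequence_io <- function(sq) {
  st <- sq$initial_state
  X <- matrix(0, length(sq$actions), 2L * N_OBJ_FEAT)
  y <- integer(length(sq$actions))
  for (i in seq_along(sq$actions)) {
    X[i, ] <- encode_io(st)$input
    y[i] <- match(sq$actions[i], ACTIONS) - 1L
    st <- step_world(st, sq$actions[i])$state
  }
  list(inputs = X, targets = y)
}

#' Train an SRN on the beverage corpus
#'
#' Backpropagation through time over each of the six whole sequences plus
#' online presentation of every one-step background item, per epoch, with
#' momentum.  Training stops with an error if the loss diverges.
#'
#' @param config An \code{srn_config}.
#' @param corpus A \code{task_corpus}.
#' @param seed Integer seed for weight initialisation.
#' @param epochs Optional override of the config's epoch count.
#' @return A trained \code{srn_net} with a per-epoch \code{loss_trace}
#'   (summed cross-entropy).
#' @export
train_srn <- function(config = srn_config(), corpus, seed = 1L, epochs = NULL) {
  stopifnot(inherits(config, "srn_config"), inherits(corpus, "task_corpus"))
  if (is.null(epochs)) epochs <- config$epochs
  net <- init_srn(config, seed)
  if (epochs == 0L) return(net)
  io <- lapply(corpus$sequences, sequence_io)
  bg_X <- corpus$background$inputs
  storage.mode(bg_X) <- "double"
  bg_y <- match(corpus$background$actions, ACTIONS) - 1L
  old_rng <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_rng))
  set.seed(as.integer(seed))
  fit <- srn_train_cpp(net$W_ih, net$W_ch, net$W_ho, net$b_h, net$b_o,
                       lapply(io, `[[`, "inputs"),
                       lapply(io, `[[`, "targets"),
                       bg_X, bg_y, as.integer(epochs),
                       config$learning_rate, config$momentum,
                       config$context_init,
                       if (is.null(config$background_weight)) 1.0 else config$background_weight,
                       if (is.null(config$train_noise_sd)) 0.0 else config$train_noise_sd)
  net$W_ih <- fit$W_ih; net$W_ch <- fit$W_ch; net$W_ho <- fit$W_ho
  net$b_h <- as.numeric(fit$b_h); net$b_o <- as.numeric(fit$b_o)
  net$loss_trace <- as.numeric(fit$loss_trace)
  net$trained <- TRUE
  net
}

#' Train an SRN until it reproduces all training sequences
#'
#' Cohort inclusion criterion: a trained network must reproduce all six
#' training sequences (\code{\link{verify_sequences}}).  A minority of
#' weight initialisations do not reach that criterion within the epoch
#' budget; this wrapper retrains from derived seeds until one does (or
#' \code{max_attempts} is exhausted, with a warning).
#'
#' @inheritParams train_srn
#' @param max_attempts Maximum training attempts (default 4).
#' @return A trained \code{srn_net}; \code{$attempts} records how many
#'   initialisations were needed.
#' @export
train_srn_verified <- function(config = srn_config(), corpus, seed = 1L,
                               epochs = NULL, max_attempts = 4L) {
  for (k in seq_len(max_attempts)) {
    use <- if (k == 1L) as.integer(seed) else derive_seed(seed, "retrain", k)
    net <- train_srn(config, corpus, seed = use, epochs = epochs)
    net$attempts <- k
    if (all(verify_sequences(net, corpus))) return(net)
  }
  warning("network did not reproduce all sequences after ", max_attempts,
          " attempts")
  net
}

#' Train a cohort of SRNs with distinct seeds
#'
#' Each network is trained to the sequence-reproduction criterion via
#' \code{\link{train_srn_verified}}.
#'
#' @param n Number of networks (the study-scale cohort is 12).
#' @param corpus A \code{task_corpus}.
#' @param config An \code{srn_config}.
#' @param epochs Optional epoch override.
#' @param master_seed Master seed from which per-network seeds derive.
#' @return List of trained \code{srn_net}s.
#' @export
train_srn_cohort <- function(n = 12L, corpus, config = srn_config(),
                             epochs = NULL, master_seed = 1L) {
  lapply(seq_len(n), function(i)
    train_srn_verified(config, corpus,
                       seed = derive_seed(master_seed, "srn", i),
                       epochs = epochs))
}

#' Run one free-running episode
#'
#' Steps the environment with argmax-selected actions until \code{say_done}
#' or the step cap.  With an \code{\link{activation_noise}} injector,
#' independent zero-mean Gaussian noise is added to the context activations
#' at every step; with \code{sigma = 0} (or no injector) runs are
#' deterministic and identical across calls with the same seed.
#'
#' @param net A trained (or lesioned) \code{srn_net}.
#' @param initial_state A \code{world_state} (e.g. from
#'   \code{\link{world_initial_state}}); alternatively pass \code{task} and
#'   let the episode seed choose the sugar source.
#' @param noise An \code{activation_noise} injector or NULL.
#' @param seed Episode seed (controls noise draws and, when
#'   \code{initial_state} is NULL, the sugar source).
#' @param task Used when \code{initial_state} is NULL.
#' @param max_steps Step cap (default from config).
#' @return A list of class \code{episode_trace}: \code{actions},
#'   \code{anomalies}, \code{task}, \code{sugar_source}, \code{completed}
#'   (reached say_done), \code{hidden} (step x n_hidden matrix),
#'   \code{seed}.
#' @export
run_episode <- function(net, initial_state = NULL, noise = NULL, seed = 1L,
                        task = c("coffee", "tea"),
                        max_steps = net$config$max_run_steps) {
  stopifnot(inherits(net, "srn_net"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (is.null(initial_state)) {
    task <- match.arg(task)
    source <- if (runif(1) < 0.5) "packet" else "bowl"
    initial_state <- world_initial_state(task, source)
  }
  sigma <- if (is.null(noise)) 0 else noise$sigma
  st <- initial_state
  ctx <- rep(net$config$context_init, net$config$n_hidden)
  actions <- character(0); anomalies <- logical(0)
  hidden <- matrix(NA_real_, max_steps, net$config$n_hidden)
  for (t in seq_len(max_steps)) {
    if (sigma > 0) ctx <- ctx + rnorm(length(ctx), 0, sigma)
    x <- encode_io(st)$input
    h <- plogis(net$b_h + drop(x %*% net$W_ih) + drop(ctx %*% net$W_ch))
    a <- ACTIONS[which.max(net$b_o + drop(h %*% net$W_ho))]
    out <- step_world(st, a)
    actions <- c(actions, a)
    anomalies <- c(anomalies, out$anomaly)
    hidden[t, ] <- h
    st <- out$state
    ctx <- h
    if (st$done) break
  }
  structure(list(actions = actions, anomalies = anomalies,
                 task = initial_state$task,
                 sugar_source = initial_state$source,
                 completed = st$done,
                 hidden = hidden[seq_along(actions), , drop = FALSE],
                 seed = as.integer(seed)),
            class = "episode_trace")
}

#' Verify that a network reproduces all training sequences
#'
#' Teacher-forced check: stepping the world along each training sequence,
#' the network's argmax action at every step must either equal the target
#' action or begin an alternative valid realization of the same task and
#' sugar source sharing the history so far (the sugar/cream order choice in
#' coffee is a genuine branch point at which either continuation counts as
#' correct).
#'
#' @param net A trained \code{srn_net}.
#' @param corpus The \code{task_corpus}.
#' @return Named logical vector, one entry per training sequence.
#' @export
verify_sequences <- function(net, corpus) {
  res <- logical(length(corpus$sequences))
  names(res) <- names(corpus$sequences)
  for (nm in names(corpus$sequences)) {
    sq <- corpus$sequences[[nm]]
    valid <- valid_realizations(corpus, sq$task, sq$sugar_source)
    st <- sq$initial_state
    ctx <- rep(net$config$context_init, net$config$n_hidden)
    ok <- TRUE
    for (i in seq_along(sq$actions)) {
      x <- encode_io(st)$input
      h <- plogis(net$b_h + drop(x %*% net$W_ih) + drop(ctx %*% net$W_ch))
      a <- ACTIONS[which.max(net$b_o + drop(h %*% net$W_ho))]
      allowed <- unique(vapply(
        Filter(function(v) length(v) >= i &&
                 identical(v[seq_len(i - 1L)], sq$actions[seq_len(i - 1L)]),
               valid),
        function(v) v[i], character(1)))
      if (!a %in% allowed) { ok <- FALSE; break }
      st <- step_world(st, sq$actions[i])$state
      ctx <- h
    }
    res[nm] <- ok
  }
  res
}

#' @export
print.srn_net <- function(x, ...) {
  cat(sprintf("srn_net: %d-%d-%d%s (seed %d)\n", x$config$n_input,
              x$config$n_hidden, x$config$n_output,
              if (isTRUE(x$trained)) ", trained" else ", untrained", x$seed))
  invisible(x)
}

#' @export
print.episode_trace <- function(x, ...) {
  cat(sprintf("episode_trace: %s (%s sugar), %d steps, %s\n", x$task,
              x$sugar_source, length(x$actions),
              if (x$completed) "completed" else "not completed"))
  invisible(x)
}
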