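# Case study 2 analyses: episode classification against the subtask
# grammar, survival curves, damage sweeps over the five lesion kinds, crux
# analysis and the weight-scaling failure-onset search.
#
# Classification operationalisation: the produced action sequence is
# segmented into complete subtask templates by a dynamic program that
# maximises the number of actions covered by template matches (ties broken
# deterministically: template match preferred over junk, templates in
# inventory order).  The matched goal sequence is then compared with the
# task's goal inventory: missing goals are omissions, out-of-task goals
# intrusions, repeats perseverations, order violations displacements;
# uncovered actions are within-subtask errors and count as independent
# actions (they support no completed crux).

# Maximal-coverage segmentation of an action sequence into subtask
# templates; returns covered length, segments and junk indices.
segment_actions <- function(actions, templates) {
  n <- length(actions)
  tnames <- names(templates)
  best <- integer(n + 1L)         # best covered count for prefix
  choice <- vector("list", n + 1L)
  for (i in seq_len(n)) {
    # default: action i is junk
    best[i + 1L] <- best[i]
    choice[[i + 1L]] <- list(kind = "junk")
    for (tn in tnames) {
      ta <- templates[[tn]]$actions
      L <- length(ta)
      if (i >= L && identical(actions[(i - L + 1L):i], ta)) {
        cand <- best[i - L + 1L] + L
        if (cand > best[i + 1L]) {
          best[i + 1L] <- cand
          choice[[i + 1L]] <- list(kind = "template", name = tn, len = L)
        }
      }
    }
  }
  segments <- list(); junk <- integer(0)
  i <- n
  while (i > 0L) {
    ch <- choice[[i + 1L]]
    if (ch$kind == "junk") {
      junk <- c(i, junk)
      i <- i - 1L
    } else {
      segments <- c(list(list(template = ch$name, start = i - ch$len + 1L,
                              end = i)), segments)
      i <- i - ch$len
    }
  }
  list(covered = best[n + 1L], segments = segments, junk = junk)
}

# longest common subsequence length of two character vectors
lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  M <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    M[i + 1L, j + 1L] <- if (a[i] == b[j]) M[i, j] + 1L else
      max(M[i, j + 1L], M[i + 1L, j])
  }
  M[na + 1L, nb + 1L]
}

#' Classify one episode against the subtask grammar
#'
#' Segments the produced action sequence into complete subtask templates,
#' then labels subtask-level errors (omission, intrusion, perseveration,
#' displacement, within-subtask) and action-level errors (omission,
#' sequence, other) from an alignment with the nearest valid realization.
#' Also counts independent actions (those covered by no completed subtask)
#' and flags each action-level error as crux or non-crux.
#'
#' @param trace An \code{episode_trace} (or a list with \code{actions},
#'   \code{task}, \code{sugar_source}).
#' @param corpus The \code{task_corpus}.
#' @return A list of class \code{episode_labels}; \code{erroneous} is TRUE
#'   unless the episode equals a valid realization.
#' @export
classify_episode <- function(trace, corpus) {
  stopifnot(inherits(corpus, "task_corpus"))
  actions <- trace$actions
  task <- trace$task
  source <- trace$sugar_source
  valid <- valid_realizations(corpus, task, source)
  if (length(valid) == 0L) stop("no valid realizations for task ", task)
  erroneous <- !any(vapply(valid, identical, logical(1), actions))
  templates <- corpus$grammar$templates
  seg <- segment_actions(actions, templates)
  produced_goals <- vapply(seg$segments, function(s)
    templates[[s$template]]$goal, character(1))
  seg_tasks <- vapply(seg$segments, function(s)
    templates[[s$template]]$task, character(1))
  goal_orders <- corpus$grammar$goal_orders[[task]]
  task_goals <- goal_orders[[1]]

  intrusion <- sum(!produced_goals %in% task_goals)
  # an in-task goal realized through the other task's routine is a
  # non-canonical execution of the subtask
  foreign_variant <- sum(produced_goals %in% task_goals &
                           !(seg_tasks %in% c(task, "both")))
  in_task <- produced_goals[produced_goals %in% task_goals]
  counts <- table(factor(in_task, levels = task_goals))
  perseveration <- sum(pmax(counts - 1L, 0L))
  omission <- sum(counts == 0L)
  kept <- in_task[!duplicated(in_task)]
  displacement <- if (length(kept)) {
    length(kept) - max(vapply(goal_orders, function(g)
      lcs_length(kept, g), integer(1)))
  } else 0L
  # within-subtask errors: actions covered by no complete template (each
  # stray action is one piece of within-subtask disorganisation) plus any
  # in-task subtask executed through the other task's routine
  within_subtask <- length(seg$junk) + foreign_variant

  # action-level alignment against the nearest valid realization
  al <- align_nearest(actions, valid)
  crux_flags <- crux_lookup(al$reference, corpus, task, source)
  act <- classify_action_ops(al$ops, actions, al$reference, crux_flags)

  structure(list(
    erroneous = erroneous, task = task, sugar_source = source,
    subtask = c(omission = omission, intrusion = intrusion,
                perseveration = perseveration, displacement = displacement,
                within_subtask = within_subtask),
    action = act$counts,
    crux_errors = act$crux, non_crux_errors = act$non_crux,
    independent_actions = length(seg$junk),
    n_actions = length(actions),
    segments = seg$segments
  ), class = "episode_labels")
}

# Levenshtein alignment (deterministic backtrace preference:
# match/substitute, then delete, then insert) against each valid
# realization; returns ops for the nearest one.
align_ops <- function(a, b) {
  na <- length(a); nb <- length(b)
  D <- matrix(0L, na + 1L, nb + 1L)
  D[, 1L] <- 0:na; D[1L, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    D[i + 1L, j + 1L] <- min(D[i, j] + (a[i] != b[j]),
                             D[i, j + 1L] + 1L, D[i + 1L, j] + 1L)
  }
  ops <- list(); i <- na; j <- nb
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && D[i + 1L, j + 1L] == D[i, j] + (a[i] != b[j])) {
      if (a[i] != b[j])
        ops <- c(list(list(op = "sub", pos_a = i, pos_b = j)), ops)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      ops <- c(list(list(op = "ins", pos_a = i, pos_b = j)), ops)  # extra action
      i <- i - 1L
    } else {
      ops <- c(list(list(op = "del", pos_a = i, pos_b = j)), ops)  # missing action
      j <- j - 1L
    }
  }
  list(dist = D[na + 1L, nb + 1L], ops = ops)
}

align_nearest <- function(actions, valid) {
  als <- lapply(valid, function(v) align_ops(actions, v))
  best <- which.min(vapply(als, `[[`, numeric(1), "dist"))
  list(reference = valid[[best]], ops = als[[best]]$ops)
}

# crux flag per position of a reference realization
crux_lookup <- function(reference, corpus, task, source) {
  keep <- vapply(corpus$sequences, function(sq)
    sq$task == task && sq$sugar_source == source &&
      identical(sq$actions, reference), logical(1))
  sq <- corpus$sequences[[which(keep)[1]]]
  sq$crux
}

classify_action_ops <- function(ops, actions, reference, crux_flags) {
  counts <- c(omission = 0L, sequence = 0L, other = 0L)
  crux <- 0L; non_crux <- 0L
  for (op in ops) {
    is_crux <- FALSE
    if (op$op == "del") {
      counts["omission"] <- counts["omission"] + 1L
      is_crux <- crux_flags[op$pos_b]
    } else if (op$op == "ins") {
      a <- actions[op$pos_a]
      recent <- actions[max(1L, op$pos_a - 5L):max(1L, op$pos_a - 1L)]
      upcoming <- reference[op$pos_b + seq_len(min(5L, max(0L, length(reference) - op$pos_b)))]
      if (a %in% recent || a %in% upcoming) {
        counts["sequence"] <- counts["sequence"] + 1L  # perseveration/anticipation
      } else {
        counts["other"] <- counts["other"] + 1L
      }
    } else {
      counts["other"] <- counts["other"] + 1L          # substitution
      is_crux <- crux_flags[op$pos_b]
    }
    if (is_crux) crux <- crux + 1L else non_crux <- non_crux + 1L
  }
  list(counts = counts, crux = crux, non_crux = non_crux)
}

# step of first divergence from the closest valid realization (Inf if the
# episode equals one of them)
first_divergence <- function(actions, valid) {
  if (any(vapply(valid, identical, logical(1), actions))) return(Inf)
  max(vapply(valid, function(v) {
    n <- min(length(v), length(actions))
    bad <- which(actions[seq_len(n)] != v[seq_len(n)])
    if (length(bad)) bad[1] else n + 1L
  }, numeric(1)))
}

#' Survival curves over a set of episodes
#'
#' For each task and step index, the proportion of episodes still
#' error-free through that step, where an episode's failure step is its
#' first divergence from the nearest valid realization of its task and
#' sugar source (so the legitimate sugar/cream order variation in coffee
#' never counts as an error).
#'
#' @param episodes List of \code{episode_trace}s (optionally with a
#'   \code{network} attribute set by the sweep helpers).
#' @param corpus The \code{task_corpus}.
#' @return Data.frame: task, network, step, surviving (proportion).
#' @export
survival_analysis <- function(episodes, corpus) {
  if (length(episodes) == 0L) stop("need at least one episode")
  rows <- lapply(episodes, function(e) {
    valid <- valid_realizations(corpus, e$task, e$sugar_source)
    data.frame(task = e$task,
               network = if (is.null(e$network)) 1L else e$network,
               fail_step = first_divergence(e$actions, valid))
  })
  df <- do.call(rbind, rows)
  out <- list()
  for (task in unique(df$task)) {
    steps <- seq_len(if (task == "coffee") 37L else 20L)
    for (net in unique(df$network[df$task == task])) {
      fs <- df$fail_step[df$task == task & df$network == net]
      out[[paste(task, net)]] <- data.frame(
        task = task, network = net, step = steps,
        surviving = vapply(steps, function(k) mean(fs > k), numeric(1)))
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("survival_curve", "data.frame")
  res
}

#' Reference severity ladders for the sequential-action damage sweep
#'
#' Geometric ladders around the reference mild settings: activation noise
#' SD 0.10; weight noise, connection severing and context-unit removal at
#' 5\% (0.05) on the recurrent (context-to-hidden) pathway.  The
#' perturbation operator adds uniform noise, so its half-ranges are the
#' reference Gaussian standard deviations times sqrt(3) (a U(-r, r)
#' variable has standard deviation r/sqrt(3)).
#'
#' @return Named list of severity vectors.
#' @export
action_severity_ladders <- function() {
  list(activation_noise = c(0.05, 0.10, 0.20, 0.40),
       perturb = sqrt(3) * c(0.05, 0.10, 0.20, 0.40),
       sever = c(0.025, 0.05, 0.10, 0.20),
       ablate = c(0.025, 0.05, 0.10, 0.20))
}

run_task_episodes <- function(nets, corpus, noise = NULL,
                              tasks = c("coffee", "tea"),
                              episodes_per_net = 100L, master_seed = 1L) {
  episodes <- list()
  for (n in seq_along(nets)) {
    for (task in tasks) {
      for (i in seq_len(episodes_per_net)) {
        e <- run_episode(nets[[n]], noise = noise,
                         seed = derive_seed(master_seed, paste0("ep_", task, "_", n), i),
                         task = task)
        e$network <- n
        episodes[[length(episodes) + 1L]] <- e
      }
    }
  }
  episodes
}

#' Damage sweep over the five lesion kinds
#'
#' For each damage kind, severity level, network and episode: applies a
#' fresh lesion draw (stochastic weight lesions are redrawn per episode;
#' activation noise is injected per step), runs a free episode of each
#' task, classifies it, and aggregates error counts.
#'
#' @param nets List of trained \code{srn_net}s.
#' @param corpus The \code{task_corpus}.
#' @param severities Named list of severity vectors (default
#'   \code{\link{action_severity_ladders}}).
#' @param tasks Tasks to run.
#' @param episodes_per_cell Episodes per (kind, severity, network, task).
#' @param master_seed Master seed.
#' @param lesion_target Weight matrices damaged by the weight-lesion kinds
#'   (default "recurrent": the context-to-hidden pathway).
#' @return A list of class \code{error_report}: \code{aggregates} (tidy
#'   data.frame of counts) and \code{episodes_per_cell}.
#' @export
damage_sweep <- function(nets, corpus, severities = action_severity_ladders(),
                         tasks = c("coffee", "tea"), episodes_per_cell = 100L,
                         master_seed = 1L, lesion_target = "recurrent") {
  if (length(nets) == 0L) stop("empty network cohort")
  rows <- list()
  for (kind in names(severities)) {
    for (sev in severities[[kind]]) {
      for (n in seq_along(nets)) {
        for (task in tasks) {
          tot <- c(omission = 0, intrusion = 0, perseveration = 0,
                   displacement = 0, within_subtask = 0)
          act_tot <- c(omission = 0, sequence = 0, other = 0)
          crux <- 0; non_crux <- 0; indep <- 0; n_act <- 0; n_err <- 0
          n_clean_subtask <- 0L; n_disorganised <- 0L
          for (i in seq_len(episodes_per_cell)) {
            sd_i <- derive_seed(master_seed,
                                paste(kind, sev, n, task, sep = "_"), i)
            if (kind == "activation_noise") {
              dn <- nets[[n]]
              e <- run_episode(dn, noise = activation_noise(sev),
                               seed = sd_i, task = task)
            } else {
              dn <- lesion_by_kind(nets[[n]], kind, sev, sd_i,
                                   target = lesion_target)
              e <- run_episode(dn, seed = sd_i, task = task)
            }
            lab <- classify_episode(e, corpus)
            if (lab$erroneous) {
              n_err <- n_err + 1L
              # clean form: every produced action lies inside a completed
              # subtask routine (errors are whole-subtask events)
              if (lab$independent_actions == 0L)
                n_clean_subtask <- n_clean_subtask + 1L
              else n_disorganised <- n_disorganised + 1L
            }
            tot <- tot + lab$subtask
            act_tot <- act_tot + lab$action
            crux <- crux + lab$crux_errors
            non_crux <- non_crux + lab$non_crux_errors
            indep <- indep + lab$independent_actions
            n_act <- n_act + lab$n_actions
          }
          rows[[length(rows) + 1L]] <- data.frame(
            kind = kind, severity = sev, network = n, task = task,
            n_episodes = episodes_per_cell, n_erroneous = n_err,
            n_clean_subtask = n_clean_subtask,
            n_disorganised = n_disorganised,
            sub_omission = tot[["omission"]],
            sub_intrusion = tot[["intrusion"]],
            sub_perseveration = tot[["perseveration"]],
            sub_displacement = tot[["displacement"]],
            within_subtask = tot[["within_subtask"]],
            act_omission = act_tot[["omission"]],
            act_sequence = act_tot[["sequence"]],
            act_other = act_tot[["other"]],
            crux_errors = crux, non_crux_errors = non_crux,
            independent_actions = indep, total_actions = n_act,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(aggregates = do.call(rbind, c(rows, make.row.names = FALSE)),
                 episodes_per_cell = episodes_per_cell),
            class = "error_report")
}

#' Crux / independent-action analysis of a damage sweep
#'
#' @param report An \code{error_report} from \code{\link{damage_sweep}}.
#' @return Data.frame per kind and severity: proportion of independent
#'   actions, crux- and non-crux-error proportions (per action), and the
#'   non-crux to crux ratio.
#' @export
crux_analysis <- function(report) {
  agg <- report$aggregates
  out <- list()
  for (kind in unique(agg$kind)) {
    for (sev in unique(agg$severity[agg$kind == kind])) {
      d <- agg[agg$kind == kind & agg$severity == sev, ]
      n_act <- sum(d$total_actions)
      crux <- sum(d$crux_errors); noncrux <- sum(d$non_crux_errors)
      out[[paste(kind, sev)]] <- data.frame(
        kind = kind, severity = sev,
        independent_prop = sum(d$independent_actions) / max(n_act, 1),
        crux_error_prop = crux / max(n_act, 1),
        non_crux_error_prop = noncrux / max(n_act, 1),
        non_crux_to_crux = if (crux > 0) noncrux / crux else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Weight-scaling failure-onset search
#'
#' Weight scaling is deterministic, so a single episode per network, task,
#' sugar source and scaling factor suffices.  Returns, per task, the
#' largest scaling factor at which any episode fails (produces a sequence
#' that is not a valid realization).
#'
#' @param nets List of trained \code{srn_net}s.
#' @param corpus The \code{task_corpus}.
#' @param s_grid Descending grid of scaling factors.
#' @param lesion_target Matrices to scale (default all trainable).
#' @return A list: \code{onset} (named numeric per task; NA if no failure
#'   on the grid) and \code{detail} (data.frame task, s, n_failures, and
#'   whether all erroneous episodes were pure omissions).
#' @export
scaling_threshold_search <- function(nets, corpus,
                                     s_grid = seq(0.99, 0.30, by = -0.01),
                                     lesion_target = "all") {
  if (is.unsorted(rev(s_grid))) stop("s_grid must be descending")
  rows <- list()
  for (task in c("coffee", "tea")) {
    for (s in s_grid) {
      nf <- 0L; omission_only <- TRUE
      for (n in seq_along(nets)) {
        dn <- scale_weights(nets[[n]], s, target = lesion_target)
        for (source in c("packet", "bowl")) {
          e <- run_episode(dn, world_initial_state(task, source))
          lab <- classify_episode(e, corpus)
          if (lab$erroneous) {
            nf <- nf + 1L
            extra <- lab$subtask[["intrusion"]] + lab$subtask[["perseveration"]] +
              lab$subtask[["displacement"]] + lab$action[["sequence"]]
            if (extra > 0) omission_only <- FALSE
          }
        }
      }
      rows[[paste(task, s)]] <- data.frame(task = task, s = s,
                                           n_failures = nf,
                                           omission_only = omission_only,
                                           stringsAsFactors = FALSE)
    }
  }
  detail <- do.call(rbind, c(rows, make.row.names = FALSE))
  onset <- vapply(c(coffee = "coffee", tea = "tea"), function(task) {
    d <- detail[detail$task == task & detail$n_failures > 0, ]
    if (nrow(d)) max(d$s) else NA_real_
  }, numeric(1))
  list(onset = onset, detail = detail)
}
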