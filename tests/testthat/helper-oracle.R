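# Brute-force reference for the subtask classifier: enumerates every
# possible segmentation of a (short) action sequence into template matches
# and junk actions by plain recursion, keeps the maximal-coverage
# segmentation under the same deterministic preference order as the
# package classifier (template match preferred over junk; templates in
# inventory order), and derives the subtask labels with independent set
# arithmetic.  Exponential, so only used on episodes of <= 25 steps.

brute_force_segment <- function(actions, templates) {
  tnames <- names(templates)
  recurse <- function(pos) {
    if (pos > length(actions)) {
      return(list(covered = 0L, segs = list(), junk = integer(0)))
    }
    # preference order: try template matches starting at pos first
    best <- NULL
    for (tn in tnames) {
      ta <- templates[[tn]]$actions
      L <- length(ta)
      if (pos + L - 1L <= length(actions) &&
          identical(actions[pos:(pos + L - 1L)], ta)) {
        rest <- recurse(pos + L)
        cand <- list(covered = rest$covered + L,
                     segs = c(list(list(template = tn, start = pos,
                                        end = pos + L - 1L)), rest$segs),
                     junk = rest$junk)
        if (is.null(best) || cand$covered > best$covered) best <- cand
      }
    }
    rest <- recurse(pos + 1L)
    cand <- list(covered = rest$covered, segs = rest$segs,
                 junk = c(pos, rest$junk))
    if (is.null(best) || cand$covered > best$covered) best <- cand
    best
  }
  recurse(1L)
}

brute_force_subtask_labels <- function(actions, task, corpus) {
  templates <- corpus$grammar$templates
  seg <- brute_force_segment(actions, templates)
  goals <- vapply(seg$segs, function(s) templates[[s$template]]$goal,
                  character(1))
  seg_tasks <- vapply(seg$segs, function(s) templates[[s$template]]$task,
                      character(1))
  orders <- corpus$grammar$goal_orders[[task]]
  task_goals <- orders[[1]]
  n_intr <- sum(!goals %in% task_goals)
  in_task <- goals[goals %in% task_goals]
  n_pers <- 0L
  n_omit <- 0L
  for (g in task_goals) {
    k <- sum(in_task == g)
    if (k == 0L) n_omit <- n_omit + 1L
    if (k > 1L) n_pers <- n_pers + (k - 1L)
  }
  firsts <- in_task[!duplicated(in_task)]
  # plain longest-common-subsequence by enumeration of subsequences of the
  # kept goal order (tiny: at most 4 goals)
  subseqs <- function(x) {
    if (!length(x)) return(list(character(0)))
    rest <- subseqs(x[-1])
    c(rest, lapply(rest, function(r) c(x[1], r)))
  }
  best_lcs <- 0L
  for (ss in subseqs(firsts)) {
    for (ord in orders) {
      # is ss a subsequence of ord?
      j <- 1L; ok <- TRUE
      for (g in ss) {
        hit <- which(ord[j:length(ord)] == g)
        if (!length(hit)) { ok <- FALSE; break }
        j <- j + hit[1]
      }
      if (ok) best_lcs <- max(best_lcs, length(ss))
    }
  }
  n_disp <- length(firsts) - best_lcs
  n_foreign <- sum(goals %in% task_goals & !(seg_tasks %in% c(task, "both")))
  n_within <- length(seg$junk) + n_foreign
  c(omission = n_omit, intrusion = n_intr, perseveration = n_pers,
    displacement = n_disp, within_subtask = n_within)
}
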