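# The simulated beverage-preparation environment: a deterministic world of
# eight objects manipulated through a fixated-object / held-object
# interface, the coffee/tea task corpus (4 coffee variants of 37 steps, 2
# tea variants of 20 steps), the subtask grammar (boundaries, crux
# actions), and a 250+ item background set of single-step affordances.

OBJECTS <- c("cup", "coffee_packet", "sugar_packet", "sugar_bowl",
             "carton", "spoon", "teabag", "lid")

ACTIONS <- c("fixate_cup", "fixate_coffee_packet", "fixate_sugar",
             "fixate_carton", "fixate_spoon", "fixate_teabag",
             "pick_up", "put_down", "tear_open", "peel_open",
             "pull_off_lid", "pour", "scoop", "dip", "stir", "sip",
             "say_done")

PORTABLE <- c("cup", "coffee_packet", "sugar_packet", "carton", "spoon", "teabag")

#' The action inventory of the beverage environment
#' @return Character vector of the 17 action identifiers, in one-hot
#'   encoding order.
#' @export
action_set <- function() ACTIONS

#' Initial world state for a task
#'
#' Coffee episodes start fixating the (sealed) coffee packet with the
#' sugar-bowl lid on; tea episodes start fixating the (wrapped) teabag
#' with the bowl already open.  The world contains a single sugar source
#' (packet or bowl): the generic \code{fixate_sugar} action fixates
#' whichever is present, which is how environmental variability enters a
#' run.
#'
#' @param task "coffee" or "tea".
#' @param sugar_source "packet" or "bowl".
#' @return A list of class \code{world_state}.
#' @export
world_initial_state <- function(task = c("coffee", "tea"),
                                sugar_source = c("packet", "bowl")) {
  task <- match.arg(task)
  sugar_source <- match.arg(sugar_source)
  structure(list(
    task = task, source = sugar_source,
    fixated = if (task == "coffee") "coffee_packet" else "teabag",
    held = "nothing",
    coffee_open = FALSE, coffee_empty = FALSE,
    sugarp_open = FALSE, sugarp_empty = FALSE,
    carton_open = FALSE, carton_empty = FALSE,
    teabag_open = FALSE, teabag_used = FALSE,
    lid_on = task == "coffee",
    spoon_loaded = FALSE,
    cup_liquid = FALSE, cup_sugar = FALSE, cup_cream = FALSE,
    cup_stirred = FALSE, sipped = FALSE, done = FALSE
  ), class = "world_state")
}

#' Advance the world by one action
#'
#' Applies the action's effect if its applicability predicate holds in the
#' current state; otherwise the state is returned unchanged with the
#' anomaly flag set.  Effects are deterministic.
#'
#' @param state A \code{world_state}.
#' @param action One of \code{action_set()}.
#' @return A list: \code{state} (new \code{world_state}) and
#'   \code{anomaly} (TRUE if the action was inapplicable).
#' @export
step_world <- function(state, action) {
  if (!action %in% ACTIONS) stop("unknown action id: ", action)
  s <- state
  ok <- TRUE
  held <- s$held
  fix <- s$fixated
  switch(action,
    fixate_cup = { s$fixated <- "cup" },
    fixate_coffee_packet = { s$fixated <- "coffee_packet" },
    fixate_sugar = {
      s$fixated <- if (s$source == "packet") "sugar_packet" else "sugar_bowl"
    },
    fixate_carton = { s$fixated <- "carton" },
    fixate_spoon = { s$fixated <- "spoon" },
    fixate_teabag = { s$fixated <- "teabag" },
    pick_up = {
      if (held == "nothing" && fix %in% PORTABLE) s$held <- fix else ok <- FALSE
    },
    put_down = {
      if (held != "nothing") s$held <- "nothing" else ok <- FALSE
    },
    tear_open = {
      if (held == "coffee_packet" && !s$coffee_open) s$coffee_open <- TRUE
      else if (held == "sugar_packet" && !s$sugarp_open) s$sugarp_open <- TRUE
      else if (held == "teabag" && !s$teabag_open) s$teabag_open <- TRUE
      else ok <- FALSE
    },
    peel_open = {
      if (held == "carton" && !s$carton_open) s$carton_open <- TRUE else ok <- FALSE
    },
    pull_off_lid = {
      if (held == "nothing" && fix == "sugar_bowl" && s$lid_on) {
        s$lid_on <- FALSE; s$held <- "lid"
      } else ok <- FALSE
    },
    pour = {
      if (held == "coffee_packet" && s$coffee_open && !s$coffee_empty) {
        s$coffee_empty <- TRUE; s$cup_liquid <- TRUE; s$cup_stirred <- FALSE
      } else if (held == "sugar_packet" && s$sugarp_open && !s$sugarp_empty) {
        s$sugarp_empty <- TRUE; s$cup_sugar <- TRUE; s$cup_stirred <- FALSE
      } else if (held == "carton" && s$carton_open && !s$carton_empty) {
        s$carton_empty <- TRUE; s$cup_cream <- TRUE; s$cup_stirred <- FALSE
      } else if (held == "spoon" && s$spoon_loaded) {
        s$spoon_loaded <- FALSE; s$cup_sugar <- TRUE; s$cup_stirred <- FALSE
      } else ok <- FALSE
    },
    scoop = {
      if (held == "spoon" && fix == "sugar_bowl" && !s$lid_on && !s$spoon_loaded)
        s$spoon_loaded <- TRUE
      else ok <- FALSE
    },
    dip = {
      if (held == "teabag" && s$teabag_open && fix == "cup") {
        s$cup_liquid <- TRUE; s$teabag_used <- TRUE; s$cup_stirred <- FALSE
      } else ok <- FALSE
    },
    stir = {
      if (held == "spoon" && fix == "cup" && s$cup_liquid)
        s$cup_stirred <- TRUE
      else ok <- FALSE
    },
    sip = {
      if (held == "cup" && s$cup_liquid) s$sipped <- TRUE else ok <- FALSE
    },
    say_done = { s$done <- TRUE }
  )
  if (!ok) s <- state
  list(state = s, anomaly = !ok)
}

# 12 feature bits per object slot: identity one-hot over the 8 objects,
# then open / empty / loaded-or-liquid / lid-on state bits.  An empty hand
# encodes as all zeros.
N_OBJ_FEAT <- 12L

object_features <- function(state, object) {
  f <- numeric(N_OBJ_FEAT)
  if (object == "nothing") return(f)
  f[match(object, OBJECTS)] <- 1
  f[9:12] <- switch(object,
    cup = c(0, !state$cup_liquid, state$cup_liquid, state$cup_stirred),
    coffee_packet = c(state$coffee_open, state$coffee_empty, 0, 0),
    sugar_packet = c(state$sugarp_open, state$sugarp_empty, 0, 0),
    sugar_bowl = c(!state$lid_on, 0, 0, state$lid_on),
    carton = c(state$carton_open, state$carton_empty, 0, 0),
    spoon = c(0, 0, state$spoon_loaded, 0),
    teabag = c(state$teabag_open, state$teabag_used, 0, 0),
    lid = c(0, 0, 0, 0)
  )
  f
}

#' Encode a world state and action for the sequence network
#'
#' Input: features of the fixated object followed by features of the held
#' object (12 bits each: identity one-hot plus open/empty/loaded state
#' bits; an empty hand is all zeros).  Output: one-hot over the 17
#' actions.
#'
#' @param state A \code{world_state}.
#' @param action An action id (optional; omit for input encoding only).
#' @return A list: \code{input} (length 24), \code{output} (length 17, or
#'   NULL if no action given).
#' @export
encode_io <- function(state, action = NULL) {
  input <- c(object_features(state, state$fixated),
             object_features(state, state$held))
  output <- NULL
  if (!is.null(action)) {
    if (!action %in% ACTIONS) stop("unknown action id: ", action)
    output <- as.numeric(ACTIONS == action)
  }
  list(input = input, output = output)
}

#' Decode a one-hot (or activation) vector to an action id
#' @param output Numeric vector of length 17.
#' @return The action id with the highest activation (lowest index on ties).
#' @export
decode_action <- function(output) {
  stopifnot(length(output) == length(ACTIONS))
  ACTIONS[which.max(output)]
}

# Subtask templates: the action blocks from which all valid sequences are
# composed. Crux = index of the goal-fulfilling action within the block.
subtask_templates <- function() {
  list(
    grounds = list(goal = "grounds", task = "coffee", crux = 5L,
      actions = c("fixate_coffee_packet", "pick_up", "tear_open",
                  "fixate_cup", "pour", "put_down", "fixate_spoon",
                  "pick_up", "fixate_cup", "stir")),
    sugar_c_packet = list(goal = "sugar", task = "coffee", crux = 6L,
      actions = c("fixate_sugar", "put_down", "pick_up", "tear_open",
                  "fixate_cup", "pour", "put_down", "fixate_spoon",
                  "pick_up", "fixate_cup", "stir")),
    sugar_c_bowl = list(goal = "sugar", task = "coffee", crux = 10L,
      actions = c("fixate_sugar", "put_down", "pull_off_lid", "put_down",
                  "fixate_spoon", "pick_up", "fixate_sugar", "scoop",
                  "fixate_cup", "pour", "stir")),
    cream = list(goal = "cream", task = "coffee", crux = 6L,
      actions = c("fixate_carton", "put_down", "pick_up", "peel_open",
                  "fixate_cup", "pour", "put_down", "fixate_spoon",
                  "pick_up", "fixate_cup", "stir")),
    steep = list(goal = "steep", task = "tea", crux = 5L,
      actions = c("fixate_teabag", "pick_up", "tear_open", "fixate_cup",
                  "dip", "put_down", "fixate_spoon", "pick_up",
                  "fixate_cup", "stir")),
    sugar_t_packet = list(goal = "sugar", task = "tea", crux = 5L,
      actions = c("fixate_sugar", "put_down", "pick_up", "tear_open",
                  "pour")),
    sugar_t_bowl = list(goal = "sugar", task = "tea", crux = 4L,
      actions = c("fixate_sugar", "scoop", "fixate_cup", "pour", "stir")),
    drink = list(goal = "drink", task = "both", crux = 4L,
      actions = c("put_down", "fixate_cup", "pick_up", "sip", "say_done"))
  )
}

#' Build the beverage task corpus and subtask grammar
#'
#' Six target sequences: four coffee variants (37 steps: add grounds, then
#' sugar and cream in either order, then drink; sugar from packet or bowl)
#' and two tea variants (20 steps: steep, add sugar from packet or bowl,
#' drink), plus a background set of 250+ single-step state/action training
#' pairs covering local affordances.  Every sequence is validated by
#' replay through the environment at build time.
#'
#' @return A list of class \code{task_corpus}: \code{sequences} (each with
#'   task, variant, sugar_source, actions, initial state, subtask goal per
#'   step, crux flag per step, boundary steps), \code{background}
#'   (data.frame of encoded inputs with target action ids), \code{grammar}
#'   (templates plus the valid goal orders per task).
#' @export
build_corpus <- function() {
  tmpl <- subtask_templates()
  compose <- function(task, source, order) {
    blocks <- switch(paste(task, order, sep = "_"),
      coffee_sugar_first = list(tmpl$grounds,
        if (source == "packet") tmpl$sugar_c_packet else tmpl$sugar_c_bowl,
        tmpl$cream, tmpl$drink),
      coffee_cream_first = list(tmpl$grounds, tmpl$cream,
        if (source == "packet") tmpl$sugar_c_packet else tmpl$sugar_c_bowl,
        tmpl$drink),
      tea_std = list(tmpl$steep,
        if (source == "packet") tmpl$sugar_t_packet else tmpl$sugar_t_bowl,
        tmpl$drink)
    )
    actions <- unlist(lapply(blocks, `[[`, "actions"))
    goals <- unlist(lapply(blocks, function(b) rep(b$goal, length(b$actions))))
    crux <- unlist(lapply(blocks, function(b) seq_along(b$actions) == b$crux))
    lens <- vapply(blocks, function(b) length(b$actions), integer(1))
    boundaries <- cumsum(lens)[-length(lens)]
    list(task = task, variant = order, sugar_source = source,
         actions = actions, goals = goals, crux = crux,
         boundaries = boundaries,
         initial_state = world_initial_state(task, source))
  }
  sequences <- list(
    coffee_sugar_first_packet = compose("coffee", "packet", "sugar_first"),
    coffee_sugar_first_bowl = compose("coffee", "bowl", "sugar_first"),
    coffee_cream_first_packet = compose("coffee", "packet", "cream_first"),
    coffee_cream_first_bowl = compose("coffee", "bowl", "cream_first"),
    tea_packet = compose("tea", "packet", "std"),
    tea_bowl = compose("tea", "bowl", "std")
  )
  # validate by replay
  for (nm in names(sequences)) {
    sq <- sequences[[nm]]
    st <- sq$initial_state
    for (i in seq_along(sq$actions)) {
      out <- step_world(st, sq$actions[i])
      if (out$anomaly) {
        stop("corpus validation failed: sequence ", nm, " step ", i,
             " (", sq$actions[i], ") is inapplicable")
      }
      st <- out$state
    }
    if (!st$done) stop("corpus validation failed: ", nm, " does not terminate")
    want <- if (sq$task == "coffee") 37L else 20L
    if (length(sq$actions) != want)
      stop("corpus validation failed: ", nm, " has ", length(sq$actions),
           " steps, expected ", want)
  }
  grammar <- list(
    templates = tmpl,
    goal_orders = list(
      coffee = list(c("grounds", "sugar", "cream", "drink"),
                    c("grounds", "cream", "sugar", "drink")),
      tea = list(c("steep", "sugar", "drink"))
    ),
    boundaries = list(coffee = c(10L, 21L, 32L), tea = c(10L, 15L))
  )
  structure(list(sequences = sequences,
                 background = build_background(),
                 grammar = grammar),
            class = "task_corpus")
}

# Canonical affordance policy over visible object features; used to
# generate the background single-step training items.
affordance_policy <- function(s) {
  held <- s$held; fix <- s$fixated
  if (held == "nothing") {
    # a sealed coffee packet / wrapped teabag under free-handed fixation is
    # the cue state that opens a whole task sequence; it is excluded from
    # the background items so the one-step set never contradicts the
    # sequence corpus at the shared neutral context
    if (fix == "coffee_packet" && !s$coffee_open) return(NA_character_)
    if (fix == "teabag" && !s$teabag_open) return(NA_character_)
    if (fix == "sugar_packet" && !s$sugarp_open) return("pick_up")
    if (fix == "sugar_bowl" && s$lid_on) return("pull_off_lid")
    if (fix == "sugar_bowl" && !s$lid_on) return("fixate_spoon")
    if (fix == "spoon") return("pick_up")
    if (fix == "cup" && s$cup_liquid) return("pick_up")
    return(NA_character_)
  }
  if (held == "coffee_packet") {
    if (!s$coffee_open) return("tear_open")
    if (!s$coffee_empty) return("pour")
    return("put_down")
  }
  if (held == "sugar_packet") {
    if (!s$sugarp_open) return("tear_open")
    if (!s$sugarp_empty) return("pour")
    return("put_down")
  }
  if (held == "carton") {
    if (!s$carton_open) return("peel_open")
    if (!s$carton_empty) return("pour")
    return("put_down")
  }
  if (held == "spoon") {
    if (s$spoon_loaded) return("pour")
    if (fix == "sugar_bowl" && !s$lid_on) return("scoop")
    if (fix == "sugar_bowl" && s$lid_on) return("put_down")
    if (fix == "sugar_packet" && !s$sugarp_open) return("put_down")
    if (fix == "carton" && !s$carton_open) return("put_down")
    if (fix == "cup" && s$cup_liquid && !s$cup_stirred) return("stir")
    if (fix == "cup" && s$cup_liquid && s$cup_stirred) return("put_down")
    return("fixate_cup")
  }
  if (held == "teabag") {
    if (!s$teabag_open) return("tear_open")
    if (fix == "cup") return("dip")
    return("fixate_cup")
  }
  if (held == "cup") {
    if (s$cup_liquid) return("sip")
    return("put_down")
  }
  if (held == "lid") return("put_down")
  NA_character_
}

build_background <- function() {
  fix_variants <- list(
    cup = list(list(cup_liquid = FALSE),
               list(cup_liquid = TRUE, cup_stirred = FALSE),
               list(cup_liquid = TRUE, cup_stirred = TRUE)),
    coffee_packet = list(list(coffee_open = FALSE),
                         list(coffee_open = TRUE, coffee_empty = FALSE),
                         list(coffee_open = TRUE, coffee_empty = TRUE)),
    sugar_packet = list(list(sugarp_open = FALSE),
                        list(sugarp_open = TRUE, sugarp_empty = FALSE),
                        list(sugarp_open = TRUE, sugarp_empty = TRUE)),
    sugar_bowl = list(list(lid_on = TRUE), list(lid_on = FALSE)),
    carton = list(list(carton_open = FALSE),
                  list(carton_open = TRUE, carton_empty = FALSE),
                  list(carton_open = TRUE, carton_empty = TRUE)),
    spoon = list(list(spoon_loaded = FALSE), list(spoon_loaded = TRUE)),
    teabag = list(list(teabag_open = FALSE),
                  list(teabag_open = TRUE, teabag_used = FALSE),
                  list(teabag_open = TRUE, teabag_used = TRUE))
  )
  held_variants <- c(list(nothing = list(list())), fix_variants[
    c("coffee_packet", "sugar_packet", "carton", "spoon", "teabag", "cup")],
    list(lid = list(list())))
  names(held_variants)[1] <- "nothing"
  names(held_variants)[length(held_variants)] <- "lid"
  inputs <- list(); targets <- character(0); keys <- character(0)
  for (fo in names(fix_variants)) for (fv in fix_variants[[fo]]) {
    for (ho in names(held_variants)) for (hv in held_variants[[ho]]) {
      if (fo == ho) next
      st <- world_initial_state("coffee", "packet")
      st$fixated <- fo
      st$held <- if (ho == "nothing") "nothing" else ho
      for (nm in names(fv)) st[[nm]] <- fv[[nm]]
      for (nm in names(hv)) st[[nm]] <- hv[[nm]]
      a <- affordance_policy(st)
      if (is.na(a)) next
      if (step_world(st, a)$anomaly) next
      enc <- encode_io(st, a)
      key <- paste(c(enc$input, a), collapse = ",")
      if (key %in% keys) next
      keys <- c(keys, key)
      inputs[[length(inputs) + 1L]] <- enc$input
      targets <- c(targets, a)
    }
  }
  list(inputs = do.call(rbind, inputs), actions = targets)
}

# All valid action realizations for a task given its sugar source.
valid_realizations <- function(corpus, task, sugar_source) {
  keep <- vapply(corpus$sequences, function(sq)
    sq$task == task && sq$sugar_source == sugar_source, logical(1))
  lapply(corpus$sequences[keep], `[[`, "actions")
}

#' @export
print.task_corpus <- function(x, ...) {
  cat("task_corpus:", length(x$sequences), "sequences,",
      nrow(x$background$inputs), "background items\n")
  invisible(x)
}
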