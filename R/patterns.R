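#' @useDynLib lesionette, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor qt runif rnorm sd aov anova pt var
#' @importFrom utils read.csv write.csv modifyList
NULL

# Layout constants for the semantic pattern sets: 216 binary units per item,
# split into a 40-unit localist name block followed by 64 visual and 112
# verbal feature units.  The 176 visual+verbal slots carry the template's
# block structure (universal / domain-shared / category-specific features).
N_NAME <- 40L
N_VISUAL <- 64L
N_VERBAL <- 112L
N_UNITS <- N_NAME + N_VISUAL + N_VERBAL
N_FEAT <- N_VISUAL + N_VERBAL

# The template's feature blocks are laid out over an abstract 1..176 slot
# axis; each block assigns a fixed number of its slots to the 64 visual
# units, the rest to the 112 verbal units.  Animal features are
# predominantly visual and artefact features predominantly verbal (the
# sensory/functional asymmetry reported for living things versus
# artefacts), which matters because naming is probed from the visual
# spokes.
CATEGORIES <- c("birds", "mammals", "fruits", "tools", "vehicles", "household")
DOMAINS <- c(birds = "animal", mammals = "animal", fruits = "animal",
             tools = "artefact", vehicles = "artefact", household = "artefact")

# Published per-category mean active-feature counts the two profiles are
# calibrated to (counts over all 216 units; the single active name unit
# contributes 1).
P1_TARGET_MEANS <- c(birds = 42.250, mammals = 41.375, fruits = 47.625,
                     tools = 25.375, vehicles = 27.500, household = 22.500)
P2_TARGET_MEANS <- c(birds = 35.875, mammals = 36.750, fruits = 31.500,
                     tools = 24.250, vehicles = 28.625, household = 24.625)

# Feature-slot block design (over the 176 visual+verbal slots), per
# profile:
#   - universal slots active with the same probability for every category,
#     offsetting the negative cross-domain correlation that disjoint
#     category/domain blocks would otherwise induce;
#   - slots shared within each domain, with a per-category probability
#     solved so the closed-form expected count hits the calibration target;
#   - category-specific slots.
# The two profiles differ in how distinctive their categories are.  In
# "P1-like", animal categories carry very few distinguishing features
# (6 slots at probability 0.2): animal items are rich (high feature
# counts) but densely packed and mutually confusable, while artefacts get
# 18 distinctive slots.  In "P2-like", every category has 12 distinctive
# slots at probability 0.8, so birds and mammals are less densely packed
# than under "P1-like" -- the structural difference that reverses the
# effect of connection severing between the two training sets.
PROFILE_LAYOUTS <- list(
  "P1-like" = list(n_univ = 24L, p_univ = 0.45, n_domain = 40L,
                   n_spec = c(animal = 6L, artefact = 18L),
                   p_spec = c(animal = 0.65, artefact = 0.5),
                   vis_univ = 24L, vis_domain = c(animal = 40L, artefact = 0L),
                   vis_spec = c(animal = 0L, artefact = 0L)),
  "P2-like" = list(n_univ = 24L, p_univ = 0.45, n_domain = 40L,
                   n_spec = c(animal = 12L, artefact = 12L),
                   p_spec = c(animal = 0.5, artefact = 0.5),
                   vis_univ = 8L, vis_domain = c(animal = 24L, artefact = 8L),
                   vis_spec = c(animal = 6L, artefact = 2L))
)

# slot -> unit-column map for a layout: the first vis_* slots of every
# block go to the visual units (41..104, in slot order), the rest to the
# verbal units (105..216)
layout_slot_map <- function(layout) {
  blocks <- list(
    c(n = layout$n_univ, v = layout$vis_univ),
    c(n = layout$n_domain, v = layout$vis_domain[["animal"]]),
    c(n = layout$n_domain, v = layout$vis_domain[["artefact"]]),
    c(n = layout$n_spec[["animal"]], v = layout$vis_spec[["animal"]]),
    c(n = layout$n_spec[["animal"]], v = layout$vis_spec[["animal"]]),
    c(n = layout$n_spec[["animal"]], v = layout$vis_spec[["animal"]]),
    c(n = layout$n_spec[["artefact"]], v = layout$vis_spec[["artefact"]]),
    c(n = layout$n_spec[["artefact"]], v = layout$vis_spec[["artefact"]]),
    c(n = layout$n_spec[["artefact"]], v = layout$vis_spec[["artefact"]])
  )
  is_visual <- unlist(lapply(blocks, function(b)
    c(rep(TRUE, b[["v"]]), rep(FALSE, b[["n"]] - b[["v"]]))))
  stopifnot(length(is_visual) == N_FEAT, sum(is_visual) == N_VISUAL)
  m <- integer(N_FEAT)
  m[is_visual] <- N_NAME + seq_len(N_VISUAL)
  m[!is_visual] <- N_NAME + N_VISUAL + seq_len(N_VERBAL)
  m
}

#' Build a semantic pattern-generation profile
#'
#' A profile fixes, for each of the six categories (three animal: birds,
#' mammals, fruits; three artefact: tools, vehicles, household), the
#' per-slot Bernoulli probability of each of the 64 visual and 112 verbal
#' features.  The two built-in profiles are calibrated so that the
#' closed-form expected number of active features per item reproduces the
#' per-category means of the two reference training sets ("P1-like" and
#' "P2-like"), while keeping within-category correlations strong,
#' within-domain correlations moderate and cross-domain correlations near
#' zero.
#'
#' @param profile_id "P1-like" or "P2-like", or a named numeric vector of
#'   six per-category target mean feature counts (over all 216 units) for a
#'   custom profile.
#' @return An object of class \code{template_profile} with elements
#'   \code{profile_id}, \code{prob} (6 x 176 matrix of feature
#'   probabilities, rows in category order), \code{categories},
#'   \code{domains} and \code{target_means}.
#' @examples
#' prof <- build_profile("P1-like")
#' feature_expectations(prof)
#' @export
build_profile <- function(profile_id) {
  if (is.character(profile_id) && length(profile_id) == 1L) {
    targets <- switch(profile_id,
      "P1-like" = P1_TARGET_MEANS,
      "P2-like" = P2_TARGET_MEANS,
      stop("unknown profile_id: '", profile_id, "' (known: 'P1-like', 'P2-like')")
    )
    id <- profile_id
  } else if (is.numeric(profile_id) && length(profile_id) == 6L) {
    targets <- profile_id
    if (is.null(names(targets))) names(targets) <- CATEGORIES
    targets <- targets[CATEGORIES]
    if (anyNA(targets)) stop("custom profile must name all six categories")
    id <- "custom"
  } else {
    stop("profile_id must be a known label or a named vector of six target means")
  }
  layout <- if (id %in% names(PROFILE_LAYOUTS)) PROFILE_LAYOUTS[[id]] else
    PROFILE_LAYOUTS[["P2-like"]]
  stopifnot(layout$n_univ + 2L * layout$n_domain + 3L * sum(layout$n_spec) == N_FEAT)
  prob <- matrix(0, 6L, N_FEAT, dimnames = list(CATEGORIES, NULL))
  idx_u <- seq_len(layout$n_univ)
  idx_dom <- list(
    animal = layout$n_univ + seq_len(layout$n_domain),
    artefact = layout$n_univ + layout$n_domain + seq_len(layout$n_domain)
  )
  spec_off <- layout$n_univ + 2L * layout$n_domain
  for (k in seq_along(CATEGORIES)) {
    cat_k <- CATEGORIES[k]
    dom_k <- DOMAINS[cat_k]
    ns <- layout$n_spec[[dom_k]]
    s_spec <- layout$p_spec[[dom_k]]
    prob[k, idx_u] <- layout$p_univ
    prob[k, spec_off + seq_len(ns)] <- s_spec
    spec_off <- spec_off + ns
    d <- (targets[k] - 1 - layout$n_univ * layout$p_univ - ns * s_spec) / layout$n_domain
    if (d < 0 || d > 1) {
      stop("target mean for ", cat_k, " (", targets[k],
           ") is not achievable under the block design")
    }
    prob[k, idx_dom[[dom_k]]] <- d
  }
  structure(
    list(profile_id = id, prob = prob, categories = CATEGORIES,
         domains = DOMAINS, target_means = targets,
         slot_map = layout_slot_map(layout)),
    class = "template_profile"
  )
}

#' Closed-form expected feature counts of a profile
#'
#' Expected number of active units per item (over all 216 units) for each
#' category: the sum of the category's feature probabilities plus one for
#' the localist name unit.
#'
#' @param profile A \code{template_profile}.
#' @return Named numeric vector of six expected counts.
#' @export
feature_expectations <- function(profile) {
  stopifnot(inherits(profile, "template_profile"))
  rowSums(profile$prob) + 1
}

#' Rescale a profile so one domain reaches a target mean feature count
#'
#' Multiplies the visual/verbal feature probabilities of the named domain's
#' three categories by a common factor (with clipping to [0, 1]) chosen so
#' that each category's expected feature count equals \code{target_mean}.
#' The other domain is untouched.  Used to ask whether raising the norms of
#' animal vectors in a "P2-like" set to "P1-like" levels restores the
#' P1-like lesioning profile.
#'
#' @param profile A \code{template_profile}.
#' @param domain "animal" or "artefact".
#' @param target_mean Desired expected active-unit count (over all 216
#'   units) for every category in the domain.
#' @return A new \code{template_profile}.
#' @export
boost_domain_norms <- function(profile, domain, target_mean) {
  stopifnot(inherits(profile, "template_profile"))
  domain <- match.arg(domain, c("animal", "artefact"))
  if (target_mean - 1 > N_FEAT || target_mean < 1) {
    stop("target_mean ", target_mean, " is not achievable (must be in [1, ",
         N_FEAT + 1, "])")
  }
  rows <- which(profile$domains[profile$categories] == domain)
  for (k in rows) {
    p <- profile$prob[k, ]
    want <- target_mean - 1
    f_of <- function(f) sum(pmin(1, f * p)) - want
    if (f_of(0) > 0) stop("target_mean below achievable range")
    # sum(pmin(1, f*p)) is continuous and nondecreasing in f; a root exists
    # whenever want <= number of nonzero slots
    hi <- 1
    while (f_of(hi) < 0) {
      hi <- hi * 2
      if (hi > 1e6) stop("target_mean ", target_mean,
                         " not achievable for category ", profile$categories[k])
    }
    f <- stats::uniroot(f_of, c(0, hi), tol = 1e-12)$root
    profile$prob[k, ] <- pmin(1, f * p)
  }
  profile$target_means[rows] <- target_mean
  profile$profile_id <- paste0(profile$profile_id, "+boost_", domain)
  profile
}

# Name-unit allocation: 48 items share a 40-unit localist name block, so 8
# within-category item pairs must share a name unit.  Four pairs fall in
# each domain (so name sharing never confounds the animal/artefact
# comparison), with the categories drawn using the set's seed (at most 4
# pairs per category).
assign_name_units <- function(seed) {
  pair_cats <- integer(0)
  repeat {
    pair_cats <- c(sample.int(3L, 4L, replace = TRUE),
                   3L + sample.int(3L, 4L, replace = TRUE))
    if (max(tabulate(pair_cats, 6L)) <= 4L) break
  }
  n_pairs <- tabulate(pair_cats, 6L)
  unit <- 0L
  name_unit <- integer(48L)
  for (k in 1:6) {
    np <- n_pairs[k]
    for (i in 1:8) {
      if (i <= 2L * np) {
        # items (1,2), (3,4), ... share a unit
        if (i %% 2L == 1L) unit <- unit + 1L
      } else {
        unit <- unit + 1L
      }
      name_unit[(k - 1L) * 8L + i] <- unit
    }
  }
  stopifnot(unit == N_NAME)
  name_unit
}

#' Generate a synthetic semantic pattern set
#'
#' Draws 48 items (8 per category) of 216 binary units each.  Every
#' visual/verbal feature is sampled independently from its category's slot
#' probability; the name block is localist, with each item's designated
#' name unit set to 1 (eight within-category item pairs share a name unit,
#' chosen with the set's seed).
#'
#' @param profile A \code{template_profile}.
#' @param seed Integer generation seed; identical seeds give bit-identical
#'   sets.
#' @return An object of class \code{pattern_set}: \code{units} (48 x 216
#'   binary matrix; columns 1-40 name, 41-104 visual, 105-216 verbal),
#'   \code{items} (data.frame with id, category, domain, name_unit),
#'   \code{profile_id} and \code{seed}.
#' @export
generate_patterns <- function(profile, seed) {
  stopifnot(inherits(profile, "template_profile"))
  seed <- as.integer(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  name_unit <- assign_name_units(seed)
  units <- matrix(0L, 48L, N_UNITS)
  cat_id <- rep(seq_along(CATEGORIES), each = 8L)
  for (i in 1:48) {
    units[i, name_unit[i]] <- 1L
    feats <- as.integer(runif(N_FEAT) < profile$prob[cat_id[i], ])
    units[i, profile$slot_map] <- feats
  }
  items <- data.frame(
    id = sprintf("%s_%d", CATEGORIES[cat_id], rep(1:8, times = 6L)),
    category = CATEGORIES[cat_id],
    domain = unname(DOMAINS[CATEGORIES[cat_id]]),
    name_unit = name_unit,
    stringsAsFactors = FALSE
  )
  structure(
    list(units = units, items = items, profile_id = profile$profile_id,
         seed = seed),
    class = "pattern_set"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Similarity diagnostics for a pattern set
#'
#' Pearson correlations between the full 216-unit item vectors, plus the
#' mean correlation within categories, within domains (between categories)
#' and across domains, and the per-category mean active-feature counts.
#'
#' @param ps A \code{pattern_set}.
#' @return A list of class \code{similarity_summary}: \code{correlation}
#'   (48 x 48), \code{block_means} (named vector: within_category,
#'   within_domain, cross_domain), \code{per_category_mean_features} and
#'   \code{degenerate_items} (indices of zero-variance items, whose
#'   correlations are reported as NA).
#' @export
similarity_summary <- function(ps) {
  stopifnot(inherits(ps, "pattern_set"))
  v <- t(ps$units)
  degenerate <- which(apply(v, 2L, function(x) var(x) == 0))
  R <- suppressWarnings(cor(v))
  diag(R) <- 1
  cat_id <- ps$items$category
  dom_id <- ps$items$domain
  ut <- upper.tri(R)
  same_cat <- outer(cat_id, cat_id, "==") & ut
  same_dom <- outer(dom_id, dom_id, "==") & !outer(cat_id, cat_id, "==") & ut
  diff_dom <- outer(dom_id, dom_id, "!=") & ut
  block_means <- c(
    within_category = mean(R[same_cat], na.rm = TRUE),
    within_domain = mean(R[same_dom], na.rm = TRUE),
    cross_domain = mean(R[diff_dom], na.rm = TRUE)
  )
  counts <- rowSums(ps$units)
  per_cat <- tapply(counts, factor(cat_id, levels = CATEGORIES), mean)
  structure(
    list(correlation = R, block_means = block_means,
         per_category_mean_features = per_cat,
         degenerate_items = degenerate),
    class = "similarity_summary"
  )
}

#' Write a pattern set to CSV (with a JSON metadata sidecar)
#'
#' One row per item: id, category, domain, name_unit, then the 216 binary
#' unit columns.  A sidecar \code{<path>.json} stores profile id and seed so
#' the round trip is lossless.
#'
#' @param ps A \code{pattern_set}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_patterns <- function(ps, path) {
  stopifnot(inherits(ps, "pattern_set"))
  m <- as.data.frame(ps$units)
  names(m) <- sprintf("u%03d", seq_len(N_UNITS))
  out <- cbind(ps$items, m)
  write.csv(out, path, row.names = FALSE)
  meta <- list(profile_id = ps$profile_id, seed = ps$seed, n_units = N_UNITS)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a pattern set written by \code{write_patterns}
#'
#' @param path CSV path.
#' @return A \code{pattern_set}.
#' @export
read_patterns <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  unit_cols <- grep("^u[0-9]+$", names(df))
  if (length(unit_cols) != N_UNITS) {
    stop("expected ", N_UNITS, " unit columns, found ", length(unit_cols))
  }
  units <- as.matrix(df[, unit_cols])
  bad <- which(!(units %in% c(0L, 1L)))
  if (length(bad)) {
    row <- ((bad[1] - 1L) %% nrow(units)) + 1L
    stop("non-binary unit value in row ", row, " of ", path)
  }
  storage.mode(units) <- "integer"
  dimnames(units) <- NULL
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list(profile_id = "unknown", seed = NA_integer_)
  structure(
    list(units = units,
         items = df[, c("id", "category", "domain", "name_unit")],
         profile_id = meta$profile_id, seed = as.integer(meta$seed)),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("pattern_set:", nrow(x$units), "items x", ncol(x$units), "units",
      sprintf("(profile %s, seed %s)\n", x$profile_id, x$seed))
  invisible(x)
}

#' @export
print.template_profile <- function(x, ...) {
  cat("template_profile:", x$profile_id, "\n")
  print(round(feature_expectations(x), 3))
  invisible(x)
}

# visual/verbal column index helpers for the 216-unit layout
name_cols <- function() seq_len(N_NAME)
visual_cols <- function() N_NAME + seq_len(N_VISUAL)
verbal_cols <- function() N_NAME + N_VISUAL + seq_len(N_VERBAL)
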