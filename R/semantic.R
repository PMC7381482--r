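# Case study 1: damage grids over trained hub networks, domain-specific
# naming-accuracy curves, area-between-curves statistics, and attractor /
# weight analyses.

#' Damage grid for the semantic lesioning study
#'
#' The four printed severity ladders: severing 2.5\% to 50\% in steps of
#' 2.5\%; uniform weight perturbation with half-range 0.05 to 1.00 in steps
#' of 0.05; unit ablation probability 0.00 to 1.00 in steps of 0.05; weight
#' scaling factor 0.75 down to 0.55 in steps of 0.01.
#'
#' @param kind One of "sever", "perturb", "ablate", "scale".
#' @param levels Optional override of the severity levels.
#' @param lesions_per_level Stochastic lesion replicates per level (default
#'   10; weight scaling is deterministic and always uses one).
#' @return A list of class \code{damage_grid}.
#' @export
damage_grid <- function(kind = c("sever", "perturb", "ablate", "scale"),
                        levels = NULL, lesions_per_level = 10L) {
  kind <- match.arg(kind)
  if (is.null(levels)) {
    levels <- switch(kind,
      sever = seq(0.025, 0.50, by = 0.025),
      perturb = seq(0.05, 1.00, by = 0.05),
      ablate = seq(0.00, 1.00, by = 0.05),
      scale = seq(0.75, 0.55, by = -0.01)
    )
  }
  if (is.unsorted(levels) && is.unsorted(rev(levels)))
    stop("severity levels must be strictly ordered")
  reps <- if (kind == "scale") 1L else as.integer(lesions_per_level)
  structure(list(kind = kind, levels = levels, lesions_per_level = reps),
            class = "damage_grid")
}

#' Run a damage grid over trained networks
#'
#' For every network, severity level and lesion replicate, damages a fresh
#' copy of the network, runs the naming protocol on all 48 items, and
#' scores accuracy per domain.
#'
#' @param nets A list of trained \code{hub_net}s (or a single network).
#' @param grid A \code{damage_grid}.
#' @param ps The \code{pattern_set} the networks were trained on.
#' @param master_seed Master seed from which all per-lesion seeds are
#'   derived.
#' @return A data.frame of class \code{accuracy_curve}: network, kind,
#'   severity, replicate, domain, accuracy.
#' @export
run_damage_grid <- function(nets, grid, ps, master_seed = 1L) {
  stopifnot(inherits(grid, "damage_grid"), inherits(ps, "pattern_set"))
  if (inherits(nets, "hub_net")) nets <- list(nets)
  for (net in nets) {
    if (net$config$n_visible != ncol(ps$units))
      stop("network / pattern set dimension mismatch")
  }
  rows <- vector("list", length(nets) * length(grid$levels) * grid$lesions_per_level)
  i <- 0L; counter <- 0L
  for (n in seq_along(nets)) {
    for (sev in grid$levels) {
      for (rep in seq_len(grid$lesions_per_level)) {
        counter <- counter + 1L
        seed <- derive_seed(master_seed, paste0("grid_", grid$kind), counter)
        damaged <- lesion_by_kind(nets[[n]], grid$kind, sev, seed)
        acc <- name_accuracy(damaged, ps)
        by_dom <- tapply(acc$correct, acc$domain, mean)
        i <- i + 1L
        rows[[i]] <- data.frame(network = n, kind = grid$kind, severity = sev,
                                replicate = rep,
                                domain = names(by_dom),
                                accuracy = as.numeric(by_dom),
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("accuracy_curve", "data.frame")
  out
}

#' Signed area between domain naming curves
#'
#' For each network, averages accuracy over lesion replicates at each
#' severity level and takes the mean over levels of (artefact - animal)
#' accuracy: the signed area between the two curves normalised by the
#' severity span.  Positive values indicate an artefact advantage
#' (artefacts named better than animals after damage).  The 95\% confidence
#' interval is a Student-t interval over the per-network areas.
#'
#' @param curve An \code{accuracy_curve} from \code{\link{run_damage_grid}}.
#' @return A list of class \code{area_result}: \code{per_network},
#'   \code{mean}, \code{sd}, \code{ci} (length-2, NA if only one network),
#'   \code{n}.
#' @export
area_between_curves <- function(curve) {
  stopifnot(is.data.frame(curve))
  agg <- stats::aggregate(accuracy ~ network + severity + domain,
                          data = curve, FUN = mean)
  wide <- stats::reshape(agg, idvar = c("network", "severity"),
                         timevar = "domain", direction = "wide")
  diff <- wide$accuracy.artefact - wide$accuracy.animal
  per_network <- tapply(diff, wide$network, mean)
  n <- length(per_network)
  m <- mean(per_network)
  if (n >= 2) {
    s <- sd(per_network)
    half <- qt(0.975, n - 1) * s / sqrt(n)
    ci <- c(m - half, m + half)
  } else {
    s <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  structure(list(per_network = as.numeric(per_network), mean = m, sd = s,
                 ci = ci, n = n),
            class = "area_result")
}

#' @export
print.area_result <- function(x, ...) {
  cat(sprintf("area (artefact - animal): mean %+0.4f (SD %0.4f), 95%% CI [%+0.4f, %+0.4f], n = %d\n",
              x$mean, x$sd, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Template-variant study
#'
#' Generates \code{n_variants} pattern sets from a profile with distinct
#' seeds, trains one network per set, damages each trained network over the
#' requested grids, and summarises the per-variant signed areas per damage
#' kind (the template-representativeness analysis).
#'
#' @param profile A \code{template_profile}.
#' @param n_variants Number of pattern-set variants (>= 2; default 20).
#' @param kinds Damage kinds to sweep (default all four).
#' @param lesions_per_level Lesion replicates per severity level.
#' @param config Hub training configuration.
#' @param epochs Optional override of training epochs.
#' @param master_seed Master seed.
#' @return A list: \code{summary} (data.frame kind, mean_area, sd_area) and
#'   \code{areas} (variant x kind matrix).
#' @export
template_variants_study <- function(profile, n_variants = 20L,
                                    kinds = c("sever", "perturb", "ablate", "scale"),
                                    lesions_per_level = 10L,
                                    config = hub_config(), epochs = NULL,
                                    master_seed = 1L) {
  if (n_variants < 2L) stop("n_variants must be >= 2")
  areas <- matrix(NA_real_, n_variants, length(kinds),
                  dimnames = list(NULL, kinds))
  for (v in seq_len(n_variants)) {
    ps <- generate_patterns(profile, seed = derive_seed(master_seed, "variant_ps", v))
    net <- init_hub(config, seed = derive_seed(master_seed, "variant_net", v))
    net <- train_hub(net, ps, epochs = epochs)
    for (k in kinds) {
      grid <- damage_grid(k, lesions_per_level = lesions_per_level)
      curve <- run_damage_grid(list(net), grid, ps,
                               master_seed = derive_seed(master_seed, paste0("variant_grid_", k), v))
      areas[v, k] <- area_between_curves(curve)$mean
    }
  }
  summary <- data.frame(kind = kinds,
                        mean_area = colMeans(areas),
                        sd_area = apply(areas, 2L, sd),
                        row.names = NULL)
  list(summary = summary, areas = areas)
}

#' Attractor summary for a trained network
#'
#' The attractor state of an item is the final hidden vector after the 2+5
#' naming protocol (visual clamp).  Returns the mean pairwise Euclidean
#' distance between attractors within each domain; smaller values indicate
#' more densely packed attractors.
#'
#' @param net A trained \code{hub_net}.
#' @param ps The \code{pattern_set}.
#' @return A list of class \code{attractor_summary}: \code{hidden} (48 x
#'   n_hidden), \code{animal_mean}, \code{artefact_mean}.
#' @export
attractor_summary <- function(net, ps) {
  out <- settle_visual_batch(net, ps$units[, visual_cols()])
  h <- out$hidden
  mean_pairwise <- function(rows) {
    if (length(rows) < 2L) stop("need >= 2 items per domain")
    d <- stats::dist(h[rows, , drop = FALSE])
    mean(d)
  }
  structure(list(
    hidden = h,
    animal_mean = mean_pairwise(which(ps$items$domain == "animal")),
    artefact_mean = mean_pairwise(which(ps$items$domain == "artefact"))
  ), class = "attractor_summary")
}

#' Two-way ANOVA on attractor densities
#'
#' Mixed-design analysis of per-network within-domain mean attractor
#' distances: pattern-set profile as a between-network factor, domain
#' (animal vs artefact) as a within-network factor.
#'
#' @param df Data.frame with columns \code{network} (unique id per trained
#'   network), \code{profile}, \code{domain}, \code{distance}.
#' @return Data.frame with rows for the profile main effect, domain main
#'   effect and interaction: F, df1, df2, p.
#' @export
attractor_anova <- function(df) {
  needed <- c("network", "profile", "domain", "distance")
  if (!all(needed %in% names(df))) {
    stop("df must have columns ", paste(needed, collapse = ", "))
  }
  tab <- table(df$network, df$domain)
  if (any(tab != 1L)) stop("each network needs exactly one distance per domain")
  df$network <- factor(df$network)
  df$profile <- factor(df$profile)
  df$domain <- factor(df$domain)
  fit <- aov(distance ~ profile * domain + Error(network/domain), data = df)
  s <- summary(fit)
  between <- s[["Error: network"]][[1]]
  within <- s[["Error: network:domain"]][[1]]
  grab <- function(tabl, term) {
    i <- grep(paste0("^", term, "\\s*$"), trimws(rownames(tabl)))
    data.frame(effect = term, F = tabl[i, "F value"],
               df1 = tabl[i, "Df"],
               df2 = tabl[nrow(tabl), "Df"],
               p = tabl[i, "Pr(>F)"], stringsAsFactors = FALSE)
  }
  out <- rbind(grab(between, "profile"),
               grab(within, "domain"),
               grab(within, "profile:domain"))
  rownames(out) <- NULL
  out
}

#' Weight-distribution summary over trained networks
#'
#' Per weight matrix: minimum, maximum, mean and proportion of positive
#' weights, averaged over networks with t-based 95\% confidence intervals.
#'
#' @param nets A list of trained \code{hub_net}s.
#' @return Data.frame: matrix, stat, mean, ci_lo, ci_hi.
#' @export
weight_summary <- function(nets) {
  if (inherits(nets, "hub_net")) nets <- list(nets)
  mats <- trainable_matrices(nets[[1]])
  rows <- list()
  for (m in mats) {
    vals <- sapply(nets, function(net) {
      w <- net[[m]]
      c(min = min(w), max = max(w), mean = mean(w), prop_positive = mean(w > 0))
    })
    for (stat in rownames(vals)) {
      x <- vals[stat, ]
      n <- length(x)
      ci <- if (n >= 2) {
        half <- qt(0.975, n - 1) * sd(x) / sqrt(n)
        c(mean(x) - half, mean(x) + half)
      } else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        matrix = m, stat = stat, mean = mean(x), ci_lo = ci[1], ci_hi = ci[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pattern and name reconstruction error by domain
#'
#' Per item, the Euclidean distance between the settled visible output
#' (2+5 naming protocol) and the target over all 216 units (pattern error)
#' and over the 40 name units only (name error); averaged per domain.
#'
#' @param net A trained \code{hub_net}.
#' @param ps The \code{pattern_set}.
#' @return Data.frame: domain, pattern_error, name_error.
#' @export
pattern_and_name_error <- function(net, ps) {
  out <- settle_visual_batch(net, ps$units[, visual_cols()])
  diff <- out$visible - ps$units
  pattern_err <- sqrt(rowSums(diff^2))
  name_err <- sqrt(rowSums(diff[, name_cols(), drop = FALSE]^2))
  data.frame(
    domain = c("animal", "artefact"),
    pattern_error = tapply(pattern_err, ps$items$domain, mean)[c("animal", "artefact")],
    name_error = tapply(name_err, ps$items$domain, mean)[c("animal", "artefact")],
    row.names = NULL
  )
}
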