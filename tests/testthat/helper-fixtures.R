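# Shared fixtures, memoised so expensive training runs once per session.
# Problem sizes follow the desk preset: 5 hub networks per profile with 5
# lesion replicates per severity level, and a 3-network SRN cohort.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

FIXTURE_SEED <- 20260927L

shared_corpus <- function() fixture("corpus", build_corpus)

shared_pattern_set <- function(profile_id) {
  fixture(paste0("ps_", profile_id), function()
    generate_patterns(build_profile(profile_id),
                      seed = derive_seed(FIXTURE_SEED, paste0("ps_", profile_id))))
}

shared_hub_cohort <- function(profile_id, n = 5L) {
  fixture(paste0("hub_", profile_id), function() {
    ps <- shared_pattern_set(profile_id)
    lapply(seq_len(n), function(i) {
      net <- init_hub(hub_config(),
                      seed = derive_seed(FIXTURE_SEED, paste0("hub_", profile_id), i))
      train_hub(net, ps)
    })
  })
}

shared_srn_cohort <- function(n = 3L) {
  fixture("srn_cohort", function() {
    corpus <- shared_corpus()
    train_srn_cohort(n = n, corpus = corpus, master_seed = FIXTURE_SEED)
  })
}

shared_grid_curve <- function(profile_id, kind) {
  fixture(paste0("curve_", profile_id, "_", kind), function() {
    nets <- shared_hub_cohort(profile_id)
    ps <- shared_pattern_set(profile_id)
    grid <- damage_grid(kind, lesions_per_level = 5L)
    run_damage_grid(nets, grid, ps,
                    master_seed = derive_seed(FIXTURE_SEED, paste0(profile_id, "_", kind)))
  })
}

# small untrained SRN used by determinism / contract tests
tiny_srn <- function(seed = 3L) {
  corpus <- shared_corpus()
  train_srn(srn_config(), corpus, seed = seed, epochs = 0L)
}

mk_trace <- function(actions, task, src) {
  list(actions = actions, task = task, sugar_source = src)
}
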