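# Shared cache for the default-study replicates used by the robustness,
# saturation and threshold acceptance checks.  Each replicate stores only
# metric tables and summaries (never the masks), so ten 40 x 16 studies fit
# comfortably in memory while being simulated once per session.

.study_cache <- new.env(parent = emptyenv())

default_study_replicates <- function(n_seeds = 10) {
  key <- paste0("rep_", n_seeds)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  out <- lapply(seq_len(n_seeds), function(s) {
    st <- simulate_study(default_study_spec(seed = s))
    masks <- lapply(st$images, `[[`, "models")
    refs <- lapply(st$images, `[[`, "reference")
    records <- evaluate_study(st)
    sub <- subsample_ensembles(masks, refs, sizes = c(2, 4, 8, 16),
                               n_rep = 10, seed = s, metrics = "dsc",
                               organ = st$images[[1]]$organ)$summary
    sweep <- if (s == 1) {
      sweep_threshold(masks, refs, grid = seq(0.05, 0.95, by = 0.05),
                      metrics = "dsc")
    }
    list(records = records, subsample = sub, sweep = sweep)
  })
  .study_cache[[key]] <- out
  out
}
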