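# shared lookup: fetch the design row matching given factor levels
get_condition <- function(rsro, sample_size, loading_profile, n_items) {
  d <- build_design()
  d[d$rsro == rsro & d$sample_size == sample_size &
      d$loading_profile == loading_profile & d$n_items == n_items, ]
}

# memoized full-design sweep shared by the acceptance tests (one ~100-rep
# run of all 36 conditions feeds every bound and cell check)
sweep_env <- new.env(parent = emptyenv())
acceptance_sweep <- function(n_reps = 100L, base_seed = 1L) {
  key <- paste0("s", n_reps, "_", base_seed)
  if (is.null(sweep_env[[key]])) {
    sweep_env[[key]] <- run_study(run_config(n_reps = n_reps,
                                             base_seed = base_seed))
  }
  sweep_env[[key]]
}

# skill-bias cell from a sweep summary
cell_bias <- function(summary, method, coefficient, rsro, sample_size,
                      loading_profile, n_items, standardized = FALSE) {
  s <- summary[summary$method == method & summary$coefficient == coefficient &
                 summary$standardized == standardized & summary$rsro == rsro &
                 summary$sample_size == sample_size &
                 summary$loading_profile == loading_profile &
                 summary$n_items == n_items, ]
  s$mean_pct_bias
}
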