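#' Run the full oral-gut typing workflow
#'
#' Chains the whole analysis on paired oral/gut tables: per-site
#' preprocessing (drop unnamed taxa, normalise counts, mean-abundance
#' prevalence filter), oral typing ([assign_ko_types]), nested gut typing
#' ([assign_koga_types]) and the type frequency table.  Identical inputs
#' and parameters give identical outputs.
#'
#' @param oral,gut [abundance_table]s (counts or relative).
#' @param meta a [sample_metadata] covering both tables.
#' @param min_mean_frac prevalence cutoff applied globally per site
#'   (default `1e-4`).
#' @param k_max largest candidate cluster number (default 10).
#' @param pseudocount JSD zero replacement.
#' @return A list: `assignments` (subject_id, ko_label, gut_label,
#'   koga_label), `ko` and `koga` (the stage results),
#'   `ko_frequencies`, `koga_frequencies`.
#' @export
run_typing_pipeline <- function(oral, gut, meta, min_mean_frac = 1e-4,
                                k_max = 10L, pseudocount = 1e-9) {
  prep <- function(t) {
    t <- drop_unnamed_taxa(t)
    if (t$mode == "counts") t <- to_relative(t)
    prevalence_filter(t, min_mean_frac)
  }
  oral_f <- prep(oral)
  gut_f <- prep(gut)
  ko <- assign_ko_types(oral_f, meta, k_max = k_max, pseudocount = pseudocount)
  koga <- assign_koga_types(gut_f, meta, ko, k_max = k_max,
                            pseudocount = pseudocount)
  list(assignments = koga$assignments, ko = ko, koga = koga,
       ko_frequencies = type_frequencies(koga$assignments$ko_label),
       koga_frequencies = type_frequencies(koga$assignments$koga_label))
}
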