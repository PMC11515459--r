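# Shared fixtures, all built in code.

# Late-PMI tibia stratum of the default synthetic study: 5 + 5 samples,
# two classes, 21 proteins (3 planted).
tibia_stratum <- function(seed) {
  study <- generate_study(synthetic_spec_default(seed = seed))
  sel <- study$meta$bone == "tibia"
  list(abundance = study$abundance[match(study$meta$sample[sel],
                                         study$abundance$sample), ],
       labels = study$meta$pmi_class[sel],
       meta = study$meta[sel, ])
}

planted_trio <- function() c("PGS1", "K1C13", "CO3A1")

# Small wide abundance tibble from a named list of sample -> values.
abundance_tbl <- function(values, proteins) {
  m <- do.call(rbind, values)
  colnames(m) <- proteins
  dplyr::bind_cols(tibble::tibble(sample = names(values)),
                   tibble::as_tibble(m))
}

# A bone-dominant study: no planted PMI signal, full detection, a large
# additive bone effect on several proteins. Used for ordination tests.
bone_dominant_spec <- function(seed) {
  spec <- synthetic_spec_default(seed = seed)
  spec$log10_mean[planted_trio(), ] <- 7
  spec$planted <- character(0)
  spec$detection_prob[, ] <- 1
  spec$bone_effect[, "tibia"] <- 0
  spec$bone_effect[c("CO1A1", "CO1A2", "CO3A1", "PGS1", "ALBU", "THRB"),
                   "tibia"] <- 1.5
  spec
}

small_config <- function() rf_config(100, 10, 2, 2, "sqrt")
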