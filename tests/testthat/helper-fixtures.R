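# Shared fixtures, built in code at test time.

# Tiny hand-written cohort rows: all schema columns, events off unless given.
toy_record <- function(patient_id = "P1", icu_events = character(0),
                       imc_events = character(0), ...) {
  row <- list(patient_id = patient_id, age = 55, sex = "female", asa = 2L,
              bmi = 26.5, weight = 78, gcs = 15L, preop_deficit = 1L,
              seizure_history = 0L, hypertension = 0L,
              coagulation_disorder = 0L, diabetes = 0L,
              cardiovascular_disease = 0L, pulmonary_disease = 0L,
              other_disease = 0L, tumor_volume = 21.5, hydrocephalus = 0L,
              midline_shift = 0L, tumor_location = "supratentorial",
              suspected_diagnosis = "meningioma", surgery_duration = 240,
              surgical_position = "supine")
  for (ev in c(icu_event_columns(), imc_event_columns())) {
    row[[ev]] <- as.integer(ev %in% c(icu_events, imc_events))
  }
  row[names(list(...))] <- list(...)
  as.data.frame(row, stringsAsFactors = FALSE)
}

toy_cohort <- function(rows) {
  as_cohort(do.call(rbind, rows), name = "toy")
}

# Cached synthetic cohorts so expensive generation runs once per size/seed.
.fixture_cache <- new.env(parent = emptyenv())
fixture_cohort <- function(n, seed = 1) {
  key <- paste0("c", n, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_cohort(generator_config(n, seed = seed))
  }
  .fixture_cache[[key]]
}

# Random combined cost matrix for derivative property checks.
random_combined_cost <- function() {
  rc <- build_rc(sort(stats::runif(3, 1, 12), decreasing = TRUE))
  f <- stats::runif(3, 0.05, 1)
  hc <- build_hc(f / sum(f))
  combine_cost(rc, hc, stats::runif(1, -5, 5))
}

# Central finite differences of the expected-cost loss.
fd_gradient <- function(z, y, C, eps = 1e-6) {
  vapply(1:3, function(j) {
    zp <- z; zm <- z
    zp[j] <- zp[j] + eps
    zm[j] <- zm[j] - eps
    (expected_cost_loss(zp, y, C) - expected_cost_loss(zm, y, C)) / (2 * eps)
  }, numeric(1))
}
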