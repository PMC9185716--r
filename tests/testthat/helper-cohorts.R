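# Shared fixtures, built in code. The default calibration is computed once
# per test run and reused wherever a cohort is drawn.
default_schema <- marsha_schema()
default_config <- generator_config()
default_calibration <- calibrate_thresholds(default_config)

draw_default_cohort <- function(n, seed) {
  cfg <- default_config
  cfg$n <- as.integer(n)
  generate_cohort(cfg, seed = seed, calibration = default_calibration)
}

# A cohort data frame of all-zero item responses.
zero_cohort <- function(n, schema = default_schema) {
  as.data.frame(matrix(0L, nrow = n, ncol = nrow(schema),
                       dimnames = list(NULL, schema$item_id)))
}

# One clean, eligible, consenting record with internally consistent QC
# metadata (zip 02215 / MA, nearby US IP, sensible text, unique key).
clean_record <- function(record_id = "r1", ...) {
  rec <- data.frame(
    record_id = record_id, age_years = 16L, us_resident = 1L,
    dated_past_year = 1L, prior_completion = 0L, skipped_count = 0L,
    timed_out = 0L, consented = 1L, zip = "02215", state = "MA",
    ip_country = "US", ip_lat = 42.4, ip_long = -71.0,
    open_text_1 = "we get along fine", open_text_2 = "met at school",
    open_text_3 = "about a year", open_text_4 = "movies together",
    open_text_5 = "nothing else", duplicate_key = paste0("k-", record_id)
  )
  override <- list(...)
  for (nm in names(override)) rec[[nm]] <- override[[nm]]
  rec
}

clean_records <- function(n) {
  do.call(rbind, lapply(seq_len(n), function(i) clean_record(paste0("r", i))))
}

test_zip_table <- read_zip_table()
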