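## Shared fixtures, built once per test run. Seed 101 is the suite's fixed
## fixture seed; individual tests that probe seed sensitivity use their own.

FIXTURE_SEED <- 101L

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

mini_cohort <- function() memo("cohort", function() {
  build_cohort("mini", seed = FIXTURE_SEED)
})

cp_table <- function() memo("cp_table", function() {
  co <- mini_cohort()
  survey_cohort(co$cp$reference$sequence, co$cp$sequences,
                co$cp$reference$annotation, co$cp$reference$layout)
})

nrdna_table <- function() memo("nrdna_table", function() {
  co <- mini_cohort()
  survey_cohort(co$nrdna$reference$sequence, co$nrdna$sequences)
})

full_run <- function() memo("full_run", function() {
  run_pipeline(pipeline_config(profile = "mini", seed = FIXTURE_SEED,
                               out_dir = file.path(tempdir(), "cpkit_fixture_run")))
})

## locus interval helper shared by marker tests
locus_interval <- function(lc) {
  switch(lc$kind,
         tr_cnv = c(lc$pos, lc$pos + lc$unit_length * lc$ref_copies - 1L),
         insertion = c(lc$pos, lc$pos + 1L),
         homopolymer = c(lc$pos, lc$pos + lc$ref_len - 1L),
         snp = c(lc$pos, lc$pos))
}
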