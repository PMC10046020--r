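# Shared fixtures. Everything is generated in code; heavier objects are
# built once per test run and cached in this environment.
fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, builder(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# An ensemble whose members return fixed constants.
constant_ensemble <- function(values) {
  members <- lapply(values, function(v) {
    structure(list(value = v), class = "constant_model")
  })
  names(members) <- paste0("const", seq_along(values))
  cpprop:::new_cpp_ensemble(members)
}

# Deterministic, untrained real ensemble: exercises the full forward path
# without any training cost. Scores are arbitrary but fixed by the seeds.
untrained_ensemble <- function() {
  cached("untrained_ensemble", function() {
    members <- lapply(default_model_specs(), function(s) {
      build_model(s, seed = 100L + s$attention_layers)
    })
    cpprop:::new_cpp_ensemble(members)
  })
}

# Small labelled peptide set for training smoke tests.
small_peptides <- function() {
  cached("small_peptides", function() {
    generate_labelled_peptides(generator_config(n_pos = 100L, n_neg = 100L,
                                                seed = 3L))
  })
}

# A small trained single-member ensemble (lightest architecture, few
# epochs) for tests needing trained behaviour.
small_trained_ensemble <- function() {
  cached("small_trained_ensemble", function() {
    frags <- fragment_peptides(small_peptides())
    spec <- default_model_specs()$Model4
    m <- train_model(build_model(spec, seed = 5L), frags,
                     train_config(epochs = 5L, seed = 5L))
    cpprop:::new_cpp_ensemble(list(Model4 = m))
  })
}

random_sequence <- function(L) {
  paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
}

wt_signal_peptide <- function() {
  tab <- read_peptide_table(system.file("extdata", "candidate_peptides.tsv",
                                        package = "cpprop"))
  tab$sequence[tab$id == "Peptide1"]
}
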