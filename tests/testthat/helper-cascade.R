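# Shared fixtures. Heavy model fits are cached so the recovery run is
# trained once and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

get_context <- function() cached("ctx", descriptor_context())

# study conditions for the planted-motif recovery run: n = 1,000 peptides,
# label noise 0.05 (generator defaults), fixed seeds
recovery_spec <- function() motif_spec(seed = 11)

get_recovery_data <- function() {
  cached("recovery_data", generate_peptides(recovery_spec()))
}

get_eval_data <- function() {
  cached("eval_data", generate_peptides(motif_spec(seed = 987)))
}

# desk-scale cascade: the three position-resolved descriptors x both
# schemes (6 slots, exhaustive 2^6 jury search), reduced grid
get_recovery_model <- function() {
  cached("recovery_model",
         cascade_fit(get_recovery_data(),
                     descriptors = c("BINAATYPE", "BINPEP", "PPCA"),
                     grid = reduced_grid_spec(), seed = 101,
                     context = get_context()))
}

# label-permutation null: same pipeline on shuffled labels
get_null_model <- function() {
  cached("null_model", {
    d <- get_recovery_data()
    set.seed(5)
    d$label <- sample(d$label)
    cascade_fit(d, descriptors = "BINPEP", grid = reduced_grid_spec(),
                seed = 77, context = get_context())
  })
}

# three-slot toy cascade state for jury-search unit tests
tiny_grid <- function() {
  grid_spec(ann_size = 3, ann_decay = 0.1, svm_kernels = "radial",
            svm_cost = 1, svm_gamma = 0.05, inner_folds = 3,
            ann_maxit = 80)
}

get_tiny_state <- function() {
  cached("tiny_state", {
    d <- generate_peptides(motif_spec(n_pos = 60, n_neg = 60, seed = 21))
    split <- split_peptides(d, 1 / 5, 3, seed = 4)
    slots <- base_slots(c("AAFREQ", "BINPEP"))[c(2, 3, 4), ]
    list(data = d, split = split,
         state = train_base_stage(d, split, slots, tiny_grid(), seed = 31,
                                  context = get_context()))
  })
}

random_peptides <- function(n, length, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = ""),
    character(1))
}
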