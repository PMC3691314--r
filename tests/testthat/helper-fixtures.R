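# standard seeded fixture shared across test files, built lazily once
.fixture_env <- new.env(parent = emptyenv())

std_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    ref <- generate_references(42)
    lib <- simulate_library(ref$truth, seed = 43) # noise-free
    cleaned <- clean_reads(lib)
    tags <- collapse_to_tags(cleaned$inserts)
    .fixture_env$fx <- list(ref = ref, lib = lib, cleaned = cleaned,
                            tags = tags)
  }
  .fixture_env$fx
}

# unannotated tag set for discovery without running the full cascade on every
# tag: only tags abundant enough to be discovery-eligible need classifying
eligible_unannotated <- function(tags, references, min_count = 45L) {
  cand <- tags[tags$count >= min_count, , drop = FALSE]
  keep <- vapply(cand$sequence, function(s) {
    classify_tag(s, references) == "unannotated"
  }, logical(1))
  cand[keep, , drop = FALSE]
}

# cascade reference list from a generate_references() result
cascade_refs <- function(ref) {
  ref$references[c("miRNA", "piRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                   "scRNA", "srpRNA", "repeat", "mRNA")]
}

# sensitivity / false accepts of discovery against the planted truth
discovery_recovery <- function(accepted, truth_mirnas) {
  novel <- truth_mirnas[truth_mirnas$role == "novel", , drop = FALSE]
  hit <- vapply(seq_len(nrow(novel)), function(i) {
    any(vapply(accepted, function(a) {
      a$chrom == novel$chrom[i] && a$start <= novel$end[i] &&
        novel$start[i] <= a$end
    }, logical(1)))
  }, logical(1))
  false_accepts <- sum(vapply(accepted, function(a) {
    !any(novel$chrom == a$chrom & novel$start <= a$end & a$start <= novel$end)
  }, logical(1)))
  list(sensitivity = mean(hit), false_accepts = false_accepts)
}
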