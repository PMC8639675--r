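# Shared fixtures: reduced problem sets and small simulated recordings so
# signal-level tests stay fast.

# n_per_cell problems from every block x operation x size cell
small_problem_set <- function(n_per_cell = 1) {
  p <- read_problem_set()
  do.call(rbind, lapply(split(p, list(p$block, p$operation, p$size)),
                        function(g) g[seq_len(n_per_cell), , drop = FALSE]))
}

# one short simulated participant (reduced problem set)
tiny_participant <- function(seed = 1, n_per_cell = 1, ...) {
  cfg <- simulation_config(n_participants = 1, seed = seed, ...)
  simulate_participant(cfg, small_problem_set(n_per_cell), 1)
}

# trials expanded from a size-by-report count table (rows large/small,
# columns procedure/retrieve/unknown)
trials_from_counts <- function(counts) {
  sizes <- rep(rownames(counts), times = rowSums(counts))
  reports <- unlist(lapply(rownames(counts), function(r)
    rep(colnames(counts), times = counts[r, ])))
  data.frame(size = sizes, report = reports, stringsAsFactors = FALSE)
}

# the printed size-by-report cross-tabulation of the study
table2_counts <- function() {
  m <- matrix(c(1080, 144, 16,
                148, 1076, 16), nrow = 2, byrow = TRUE)
  dimnames(m) <- list(c("large", "small"),
                      c("procedure", "retrieve", "unknown"))
  m
}
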