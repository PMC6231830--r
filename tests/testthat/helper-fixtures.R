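# Shared fixtures, all generated in code.

# A small but fully structured synthetic site.
mini_config <- function(...) {
  args <- list(n_villages = 4,
               village_size = list(meanlog = log(250), sdlog = 0.5,
                                   min = 60, max = 900))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

mini_site <- function(seed = 101, ...) generate_site(mini_config(...), seed)

# O(n*m) brute-force nearest-spot oracle.
brute_force_nearest <- function(households, spots, threshold = 1.0) {
  q <- spots[spots$diameter >= threshold, , drop = FALSE]
  vapply(seq_len(nrow(households)), function(i)
    min(sqrt((q$x - households$x[i])^2 + (q$y - households$y[i])^2)),
    numeric(1))
}

# Household table with an exact composition per sector.
make_households <- function(sector_counts) {
  # sector_counts: named list sector -> named caste counts
  rows <- lapply(names(sector_counts), function(s) {
    cc <- sector_counts[[s]]
    data.frame(household_id = paste0(s, seq_len(sum(cc))),
               sector_num = as.integer(s),
               caste = rep(names(cc), cc), ses = "middle",
               n_members = 4L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
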