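# Shared fixtures, built in code. small_sim() caches one desk-scale
# simulation so several test files can reuse it without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(seed = 101, ...) {
  sim_config(
    genome_size = 4e6, n_chromosomes = 2, mean_contig = 1.5e5,
    inversion = list(offset = 6e4, length = 4e4),
    novel_donor = 3e4, novel_acceptor = 1.5e4,
    n_chimeras = 2, seed = seed, ...
  )
}

small_sim <- function() {
  if (!is.null(.fixture_env$sim)) return(.fixture_env$sim)
  cfg <- small_config()
  set.seed(cfg$seed)
  ref <- simulate_reference(cfg)
  acc <- simulate_accession(ref, cfg)
  frag <- fragment_assembly(acc, cfg)
  .fixture_env$sim <- list(cfg = cfg, ref = ref, acc = acc, frag = frag)
  .fixture_env$sim
}

# brute-force Nxx: walk the sorted lengths accumulating until the threshold
nxx_oracle <- function(lengths, x = 50, genome_size = NULL) {
  gs <- if (is.null(genome_size)) sum(lengths) else genome_size
  ls <- sort(lengths, decreasing = TRUE)
  cum <- 0
  for (l in ls) {
    cum <- cum + l
    if (cum >= x / 100 * gs) return(l)
  }
  0
}

# brute-force gap scan: classify every base, then merge sub-min_contig
# islands lying between gap runs
detect_gaps_oracle <- function(seq, min_contig = 200, min_gap = 1) {
  bases <- strsplit(toupper(seq), "")[[1]]
  is_gap <- bases == "N"
  r <- rle(is_gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts, end = ends, gap = r$values)
  runs$gap[runs$gap & (runs$end - runs$start + 1) < min_gap] <- FALSE
  # islands between two gap runs shorter than min_contig become gap
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(runs))) {
      if (!runs$gap[i] && i > 1 && i < nrow(runs) &&
          runs$gap[i - 1] && runs$gap[i + 1] &&
          (runs$end[i] - runs$start[i] + 1) < min_contig) {
        runs$gap[i] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # merge adjacent same-type runs
  out <- runs[1, ]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$gap[i] == out$gap[nrow(out)]) {
      out$end[nrow(out)] <- runs$end[i]
    } else {
      out <- rbind(out, runs[i, ])
    }
  }
  out[out$gap, c("start", "end")]
}

# random alignment group for the chaining oracle: disjoint on query
random_chain_group <- function(n, max_gap = 1000) {
  q_start <- integer(n); q_end <- integer(n)
  pos <- 1
  for (i in seq_len(n)) {
    pos <- pos + sample(0:(2 * max_gap), 1)
    q_start[i] <- pos
    q_end[i] <- pos + sample(50:400, 1)
    pos <- q_end[i] + 1
  }
  t_pos <- cumsum(sample(c(-3000:-1, 1:3000), n, replace = TRUE)) + 50000
  tibble::tibble(
    query = "q", q_start = q_start, q_end = q_end, strand = "+",
    target = "t", t_start = t_pos, t_end = t_pos + (q_end - q_start),
    matches = q_end - q_start + 1
  )
}

# exhaustive best collinear chain by aligned bases (subset enumeration)
best_chain_oracle <- function(rec, max_join_gap) {
  n <- nrow(rec)
  rec <- rec[order(rec$q_start), ]
  compat <- function(j, i) {
    if (rec$q_start[i] <= rec$q_end[j]) return(FALSE)
    if (rec$q_start[i] - rec$q_end[j] - 1 > max_join_gap) return(FALSE)
    if (rec$t_start[i] <= rec$t_end[j]) return(FALSE)
    if (rec$t_start[i] - rec$t_end[j] - 1 > max_join_gap) return(FALSE)
    TRUE
  }
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) == 0) next
    ok <- TRUE
    if (length(idx) > 1) {
      for (k in seq_len(length(idx) - 1)) {
        if (!compat(idx[k], idx[k + 1])) { ok <- FALSE; break }
      }
    }
    if (ok) best <- max(best, sum(rec$matches[idx]))
  }
  best
}

# adjacency pairs (sorted, unique) from a truth join table; chimera part
# names collapse onto their parent contig
truth_pairs <- function(truth_joins) {
  strip <- function(x) sub("_p[12]$", "", x)
  out <- list()
  for (os in unique(truth_joins$output_scaffold)) {
    m <- strip(truth_joins$member[truth_joins$output_scaffold == os])
    if (length(m) < 2) next
    out[[os]] <- paste(pmin(m[-length(m)], m[-1]),
                       pmax(m[-length(m)], m[-1]))
  }
  unique(unlist(out))
}

called_pairs <- function(joins) {
  out <- purrr::map(joins$members, function(mem) {
    m <- mem$input_scaffold
    if (length(m) < 2) return(NULL)
    paste(pmin(m[-length(m)], m[-1]), pmax(m[-length(m)], m[-1]))
  })
  unique(unlist(out))
}
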