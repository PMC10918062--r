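# Shared fixtures and independent oracles, built in code at test time.

make_counts <- function(m, features = NULL, samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- features %||% rownames(m) %||% sprintf("f%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||% sprintf("s%d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_meta <- function(samples, groups) {
  data.frame(sample = samples, group = groups, stringsAsFactors = FALSE)
}

# all permutations of 1..n, built independently of the package internals
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) for (i in seq_len(n)) {
    q <- p; q[q >= i] <- q[q >= i] + 1L
    out[[length(out) + 1L]] <- c(i, q)
  }
  out
}

# brute-force two-sided Fisher exact p for [[xa, na - xa], [xb, nb - xb]]
# via direct enumeration of the hypergeometric support with choose()
fisher_oracle <- function(xa, na_, xb, nb_) {
  m <- xa + xb
  supp <- max(0, m - nb_):min(m, na_)
  prob <- choose(na_, supp) * choose(nb_, m - supp) / choose(na_ + nb_, m)
  obs <- choose(na_, xa) * choose(nb_, m - xa) / choose(na_ + nb_, m)
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# default-scale simulated run shared by the slower tests (computed once)
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "mirprop_default_run")
      cfg <- run_config(simulate = sim_config(seed = 1), seed = 1)
      res <- suppressMessages(suppressWarnings(run_pipeline(cfg, dir)))
      cache <<- list(dir = dir, fit = res$fit,
                     sim = suppressMessages(simulate_dataset(sim_config(seed = 1))))
    }
    cache
  }
})

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}
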