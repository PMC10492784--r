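# Shared fixtures and small independent oracles used across the suite.
# Everything is generated in code; no stored data.

# A tiny times table (taxon, ts, te, extinct) from explicit vectors.
make_times <- function(ts, te, extinct = rep(TRUE, length(ts))) {
  data.frame(taxon = seq_along(ts), ts = ts, te = te, extinct = extinct)
}

# Minimal occurrence records with sensible defaults for curation tests.
make_records <- function(n = 1, genus = "Genusa", primary_reso = "",
                         accepted_genus = genus, collection_no = seq_len(n),
                         max_ma = 250, min_ma = 248, stage = "Test",
                         is_international_stage = TRUE,
                         environment = "marine", lithology1 = "carbonate",
                         paleolat = 0, paleolng = 0,
                         order = "Pectinida", class = "Bivalvia") {
  data.frame(genus = genus, primary_reso = primary_reso,
             accepted_genus = accepted_genus, collection_no = collection_no,
             max_ma = max_ma, min_ma = min_ma, stage = stage,
             is_international_stage = is_international_stage,
             environment = environment, lithology1 = lithology1,
             paleolat = paleolat, paleolng = paleolng,
             order = order, class = class,
             stringsAsFactors = FALSE)
}

# Exact integral of N(t) * rate(t) for a piecewise-constant trajectory,
# computed cell by cell with exact per-cell lineage-time clipping. Exact
# at any cell width, so it is an independent oracle for the closed-form
# birth-death integral.
oracle_bd_integral <- function(ts, te, shifts, rates, window, dt = 1e-3) {
  edges <- c(window[1], shifts, window[2])
  cells <- seq(window[1], window[2], by = -dt)
  if (cells[length(cells)] > window[2]) cells <- c(cells, window[2])
  # split cells at the shift ages so the rate is constant within a cell
  cells <- sort(unique(c(cells, shifts)), decreasing = TRUE)
  a <- cells[-length(cells)]
  b <- cells[-1]
  mid <- (a + b) / 2
  idx <- findInterval(-mid, -edges)
  idx[idx < 1] <- 1
  idx[idx > length(rates)] <- length(rates)
  r <- rates[idx]
  tot <- 0
  for (i in seq_along(ts)) {
    tot <- tot + sum(r * pmax(0, pmin(ts[i], a) - pmax(te[i], b)))
  }
  tot
}

# Independent per-genus/per-bin boundary-crosser tally by brute force.
oracle_bin_counts <- function(fad, lad, bins) {
  out <- NULL
  for (j in seq_len(nrow(bins))) {
    bo <- bins$max_ma[j]
    by <- bins$min_ma[j]
    n_bt <- n_bl <- n_ft <- n_fl <- 0L
    for (i in seq_along(fad)) {
      cb <- fad[i] >= bo && lad[i] < bo
      ct <- fad[i] >= by && lad[i] < by
      ov <- fad[i] > by && lad[i] < bo
      if (cb && ct) n_bt <- n_bt + 1L
      else if (cb) n_bl <- n_bl + 1L
      else if (ct) n_ft <- n_ft + 1L
      else if (ov) n_fl <- n_fl + 1L
    }
    out <- rbind(out, data.frame(n_bt = n_bt, n_bl = n_bl,
                                 n_ft = n_ft, n_fl = n_fl))
  }
  out
}

# The analysis window used throughout: the generator's default simulation
# window minus its ~3 Myr edge buffers.
buffered_window <- c(273.0, 247.2)
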