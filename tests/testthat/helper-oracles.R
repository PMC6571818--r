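# Independent oracles used to freeze expected values: a naive
# grid-scan formula enumerator and a direct isotope-assignment
# enumerator.  Both deliberately avoid the package's own algorithms
# (mass bracketing, distribution convolution).

# Naive formula search: full expand.grid over all five element ranges,
# filtered by the raw predicates.  Returns a sorted character vector of
# Hill formula strings.
oracle_enumerate <- function(neutral_mass, cons) {
  it <- isotope_table()
  grid <- expand.grid(C = cons$c_range[1]:cons$c_range[2],
                      H = cons$h_range[1]:cons$h_range[2],
                      N = cons$n_range[1]:cons$n_range[2],
                      O = cons$o_range[1]:cons$o_range[2],
                      S = cons$s_range[1]:cons$s_range[2])
  oracle_filter_grid(neutral_mass, cons, grid)
}

# Split out so acceptance can reuse one grid across many masses.
oracle_filter_grid <- function(neutral_mass, cons, grid) {
  it <- isotope_table()
  mass <- grid$C * it$C$mass[1] + grid$H * it$H$mass[1] +
    grid$N * it$N$mass[1] + grid$O * it$O$mass[1] + grid$S * it$S$mass[1]
  dbe <- grid$C - grid$H / 2 + grid$N / 2 + 1
  hc <- grid$H / grid$C
  keep <- abs((neutral_mass - mass) / mass * 1e6) <= cons$tol_ppm &
    hc >= cons$hc_min & hc <= cons$hc_max &
    dbe >= cons$dbe_min & dbe <= cons$dbe_max
  g <- grid[keep, , drop = FALSE]
  sort(oracle_hill(g$C, g$H, g$N, g$O, g$S))
}

oracle_hill <- function(C, H, N, O, S) {
  part <- function(sym, n)
    ifelse(n == 0L, "", ifelse(n == 1L, sym, paste0(sym, n)))
  paste0(part("C", C), part("H", H), part("N", N), part("O", O),
         part("S", S))
}

# All compositions of n identical atoms over k isotope slots.
oracle_compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1))
  out <- NULL
  for (i in 0:n) {
    rest <- oracle_compositions(n - i, k - 1L)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

# Direct isotopologue enumeration: every multinomial isotope assignment
# per element, cartesian product across elements, aggregated by total
# neutron shift.  Returns data.frame(mz, rel_abundance), base = 100.
oracle_pattern <- function(f) {
  counts <- unclass(leafscreen:::.as_formula(f))
  it <- isotope_table()
  states <- list(data.frame(shift = 0L, mass = 0, prob = 1))
  for (el in names(it)) {
    n <- counts[[el]]
    if (n == 0L) next
    iso <- it[[el]]
    k <- length(iso$mass)
    comp <- oracle_compositions(n, k)
    shift_per <- as.integer(round(iso$mass - iso$mass[1]))
    el_states <- data.frame(
      shift = as.integer(comp %*% shift_per),
      mass = as.numeric(comp %*% iso$mass),
      prob = apply(comp, 1, function(cc)
        exp(lfactorial(n) - sum(lfactorial(cc)) +
              sum(cc * log(iso$abundance)))))
    states[[length(states) + 1L]] <- el_states
  }
  # cartesian product across elements
  total <- states[[1]]
  for (s in states[-1]) {
    idx <- expand.grid(a = seq_len(nrow(total)), b = seq_len(nrow(s)))
    total <- data.frame(shift = total$shift[idx$a] + s$shift[idx$b],
                        mass = total$mass[idx$a] + s$mass[idx$b],
                        prob = total$prob[idx$a] * s$prob[idx$b])
  }
  agg_p <- tapply(total$prob, total$shift, sum)
  agg_m <- tapply(total$prob * total$mass, total$shift, sum)
  shift <- as.integer(names(agg_p))
  o <- order(shift)
  data.frame(mz = (agg_m / agg_p)[o],
             rel_abundance = (agg_p / max(agg_p) * 100)[o])
}

# A measured spectrum fabricated exactly from a theoretical pattern.
spectrum_from_pattern <- function(pattern, rt = 1, base_intensity = 1e5,
                                  polarity = "pos") {
  o <- order(pattern$mz)
  centroid_spectrum(rt, pattern$mz[o],
                    pattern$rel_abundance[o] / 100 * base_intensity,
                    polarity)
}

# Bare EIC trace constructor for peak-detection tests.
make_trace <- function(rt, intensity, target_mz = 200, tol_ppm = 3) {
  structure(list(target_mz = target_mz, tol_ppm = tol_ppm,
                 rt = rt, intensity = intensity),
            class = "eic_trace")
}
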