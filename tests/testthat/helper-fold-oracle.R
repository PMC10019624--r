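# Independent folding oracle: exhaustive enumeration of all nested
# structures with an independently written loop-energy scorer. Used to
# verify the dynamic-programming MFE; deliberately shares no code with
# the package implementation.

oracle_tables <- function(model, tempK) {
  scale <- tempK / 310.15
  list(
    stackG = model$stack_dH - tempK * model$stack_dS,
    hairpinG = ifelse(is.finite(model$hairpin37),
                      model$hairpin37 * scale, Inf),
    bulgeG = model$bulge37 * scale,
    internalG = ifelse(is.finite(model$internal37),
                       model$internal37 * scale, Inf),
    ml_a = model$ml_a * scale, ml_b = model$ml_b * scale,
    ml_c = model$ml_c * scale,
    asym_per_nt = model$asym_per_nt * scale,
    asym_max = model$asym_max * scale,
    minh = model$min_hairpin, maxint = model$max_internal)
}

oracle_codes <- function(seq) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  code <- match(ch, c("A", "C", "G", "U"))
  code[ch == "N"] <- 0L
  code
}

oracle_ptype <- function(model, code, i, j) {
  if (code[i] == 0L || code[j] == 0L) return(0L)
  model$pair_type[code[i], code[j]]
}

# number of nested structures (minimum hairpin loop minh) — used to
# keep the enumeration battery tractable
oracle_count <- function(code, model) {
  n <- length(code)
  minh <- model$min_hairpin
  memo <- matrix(NA_real_, n + 1L, n + 1L)
  cnt <- function(i, j) {
    if (i >= j) return(1)
    if (!is.na(memo[i, j])) return(memo[i, j])
    total <- cnt(i + 1L, j)
    if (i + minh + 1L <= j) for (k in seq.int(i + minh + 1L, j)) {
      if (oracle_ptype(model, code, i, k) > 0L)
        total <- total + cnt(i + 1L, k - 1L) * cnt(k + 1L, j)
    }
    memo[i, j] <<- total
    total
  }
  cnt(1L, length(code))
}

# loop energy closed by pair (i, j) with top-level inner components
oracle_loop_energy <- function(tabs, model, code, i, j, comps) {
  m <- length(comps)
  if (m == 0L) {
    size <- j - i - 1L
    if (size > length(tabs$hairpinG)) return(Inf)
    return(tabs$hairpinG[size])
  }
  if (m == 1L) {
    k <- comps[[1]]$i; l <- comps[[1]]$j
    u1 <- k - i - 1L; u2 <- j - l - 1L
    if (u1 + u2 == 0L) {
      p1 <- oracle_ptype(model, code, i, j)
      p2 <- oracle_ptype(model, code, k, l)
      return(tabs$stackG[p1, p2])
    }
    if (u1 + u2 > tabs$maxint) return(Inf)
    if (u1 == 0L || u2 == 0L) return(tabs$bulgeG[u1 + u2])
    return(tabs$internalG[u1 + u2] +
             min(tabs$asym_max, tabs$asym_per_nt * abs(u1 - u2)))
  }
  unpaired <- (j - i - 1L) -
    sum(vapply(comps, function(cp) cp$j - cp$i + 1L, integer(1)))
  tabs$ml_a + tabs$ml_b * (1L + m) + tabs$ml_c * unpaired
}

# enumerate every structure of region [i, j]; each entry carries its
# top-level components (span + energy + pairs)
oracle_enum_open <- function(tabs, model, code, i, j) {
  if (i > j) return(list(list(comps = list(), energy = 0, pairs = NULL)))
  res <- oracle_enum_open(tabs, model, code, i + 1L, j)  # i unpaired
  minh <- tabs$minh
  if (i + minh + 1L <= j) for (k in seq.int(i + minh + 1L, j)) {
    if (oracle_ptype(model, code, i, k) == 0L) next
    closed <- oracle_enum_closed(tabs, model, code, i, k)
    rest <- oracle_enum_open(tabs, model, code, k + 1L, j)
    for (a in closed) for (b in rest) {
      res[[length(res) + 1L]] <- list(
        comps = c(list(list(i = i, j = k, energy = a$energy)), b$comps),
        energy = a$energy + b$energy,
        pairs = rbind(a$pairs, b$pairs))
    }
  }
  res
}

oracle_enum_closed <- function(tabs, model, code, i, j) {
  inner <- oracle_enum_open(tabs, model, code, i + 1L, j - 1L)
  lapply(inner, function(s) {
    e <- oracle_loop_energy(tabs, model, code, i, j, s$comps) + s$energy
    list(energy = e, pairs = rbind(c(i, j), s$pairs))
  })
}

# exhaustive MFE: minimum over all enumerated structures (open chain
# included at energy 0)
oracle_mfe <- function(seq, tempK, model = energy_model()) {
  code <- oracle_codes(seq)
  tabs <- oracle_tables(model, tempK)
  all_s <- oracle_enum_open(tabs, model, code, 1L, length(code))
  energies <- vapply(all_s, `[[`, numeric(1), "energy")
  min(0, energies[is.finite(energies)])
}

# random sequence whose structure count stays enumerable; longer
# sequences use a skewed composition (fewer pairable dimers) so the
# exhaustive enumeration stays feasible
oracle_battery_seq <- function(len, max_count = 30000) {
  model <- energy_model()
  prob <- if (len <= 20) c(0.3, 0.2, 0.2, 0.3) else c(0.4, 0.3, 0.2, 0.1)
  for (try in 1:100) {
    s <- paste(sample(c("A", "C", "G", "U"), len, replace = TRUE,
                      prob = prob), collapse = "")
    if (oracle_count(oracle_codes(s), model) <= max_count) return(s)
  }
  stop("no enumerable sequence found at length ", len)
}
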