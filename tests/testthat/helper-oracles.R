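# Independent brute-force oracles. All are written as plain nested loops over
# first principles so they share no code path with the package internals.

# independent atomic masses (CODATA/AME2020), used to recompute pattern deltas
oracle_atomic <- c(
  H = 1.00782503207, C12 = 12, C13 = 13.00335483507, N = 14.0030740048,
  O = 15.99491461956, Na = 22.9897692809, K = 38.96370668,
  Cl35 = 34.96885268, Cl37 = 36.96590259, S32 = 31.97207100,
  S34 = 33.96786690
)

oracle_deltas <- function() {
  a <- oracle_atomic
  c(
    "13C/12C"   = a[["C13"]] - a[["C12"]],
    "13C/12C*2" = 2 * (a[["C13"]] - a[["C12"]]),
    "37Cl/35Cl" = a[["Cl37"]] - a[["Cl35"]],
    "34S/32S"   = a[["S34"]] - a[["S32"]],
    "Na/H"      = a[["Na"]] - a[["H"]],
    "ACN"       = 2 * a[["C12"]] + 3 * a[["H"]] + a[["N"]],
    "NaCOOH"    = a[["Na"]] + a[["C12"]] + 2 * a[["O"]] + a[["H"]],
    "K/H"       = a[["K"]] - a[["H"]],
    "CH3OH"     = a[["C12"]] + 4 * a[["H"]] + a[["O"]],
    "NaCH2COOH" = a[["Na"]] + 2 * a[["C12"]] + 3 * a[["H"]] + 2 * a[["O"]]
  )
}

oracle_tol <- function(mz, ppm = 5e-6, abs_cap = 5e-4) {
  min(ppm * mz, abs_cap)
}

# O(n^2 * patterns) relation-graph scan
oracle_edges <- function(table, patterns, w, ppm = 5e-6, abs_cap = 5e-4) {
  rows <- list()
  n <- nrow(table)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (abs(table$rt[j] - table$rt[i]) > w) next
      for (k in seq_len(nrow(patterns))) {
        err <- table$mz[j] - table$mz[i] - patterns$delta[k]
        if (abs(err) > oracle_tol(table$mz[i], ppm, abs_cap)) next
        if (patterns$kind[k] == "isotope" && patterns$isotope_step[k] == 1L &&
            !(table$intensity[j] < 0.5 * table$intensity[i])) next
        rows[[length(rows) + 1L]] <- data.frame(
          from_id = table$id[i], to_id = table$id[j],
          label = patterns$label[k], mass_error = err,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(from_id = character(), to_id = character(),
                      label = character(), mass_error = numeric())
  }
  out[order(out$from_id, out$to_id, out$label), , drop = FALSE]
}

# double-loop anchor-vs-feature histogram (bin -> count)
oracle_histogram <- function(annotation, table, w, bin_size,
                             max_delta = 200, exclude_same_khipu = TRUE) {
  counts <- integer()
  kp <- setNames(rep(NA_character_, nrow(table)), table$id)
  kp[annotation$grid$feature_id] <- annotation$grid$khipu_id
  for (aid in annotation$khipus$anchor_id) {
    ai <- match(aid, table$id)
    for (j in seq_len(nrow(table))) {
      if (j == ai) next
      if (abs(table$rt[j] - table$rt[ai]) > w) next
      if (exclude_same_khipu && !is.na(kp[table$id[j]]) &&
          kp[table$id[j]] == kp[aid]) next
      d <- abs(table$mz[j] - table$mz[ai])
      if (d > max_delta) next
      b <- as.character(floor(d / bin_size))
      counts[b] <- if (is.na(counts[b])) 1L else counts[b] + 1L
    }
  }
  out <- data.frame(bin = as.integer(names(counts)), count = unname(counts))
  out[order(out$bin), , drop = FALSE]
}

# all-pairs ISF link scan with the documented one-parent-per-child rule
oracle_isf_links <- function(annotation, candidates, w, table,
                             ppm = 5e-6, abs_cap = 5e-4) {
  kh <- annotation$khipus
  ai <- match(kh$anchor_id, table$id)
  parents <- data.frame(id = kh$khipu_id, mz = table$mz[ai],
                        rt = table$rt[ai], intensity = table$intensity[ai])
  si <- match(annotation$singletons, table$id)
  kids <- rbind(
    data.frame(id = parents$id, mz = parents$mz, rt = parents$rt,
               kind = "khipu"),
    data.frame(id = annotation$singletons, mz = table$mz[si],
               rt = table$rt[si], kind = "singleton")
  )
  rows <- list()
  for (ci in seq_len(nrow(kids))) {
    best <- NULL
    for (pi in seq_len(nrow(parents))) {
      if (parents$id[pi] == kids$id[ci]) next
      if (!(kids$mz[ci] < parents$mz[pi])) next
      if (abs(kids$rt[ci] - parents$rt[pi]) > w) next
      for (k in seq_len(nrow(candidates))) {
        err <- parents$mz[pi] - kids$mz[ci] - candidates$delta[k]
        if (abs(err) > oracle_tol(parents$mz[pi], ppm, abs_cap)) next
        cand <- list(parent = parents$id[pi], child = kids$id[ci],
                     kind = kids$kind[ci], label = candidates$label[k],
                     delta = candidates$delta[k], err = err,
                     p_int = parents$intensity[pi],
                     rt_shift = kids$rt[ci] - parents$rt[pi])
        if (is.null(best) ||
            abs(cand$err) < abs(best$err) ||
            (abs(cand$err) == abs(best$err) && cand$p_int > best$p_int) ||
            (abs(cand$err) == abs(best$err) && cand$p_int == best$p_int &&
               cand$parent < best$parent)) {
          best <- cand
        }
      }
    }
    if (!is.null(best)) rows[[length(rows) + 1L]] <- as.data.frame(best)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(parent = character(), child = character(),
                      kind = character(), label = character(),
                      delta = numeric(), err = numeric(), p_int = numeric(),
                      rt_shift = numeric()))
  }
  out[order(out$parent, out$child), , drop = FALSE]
}

# triple-loop MS/MS screening statistics
oracle_msms_stats <- function(table, exemplars, w, ppm = 5e-6,
                              min_rel = 0.1, top_k = 5) {
  p_set <- character(); y_set <- character(); n_frag <- 0L
  for (s in seq_len(nrow(exemplars))) {
    prec <- exemplars$precursor_mz[s]
    feats <- which(abs(table$mz - prec) <= ppm * prec)
    if (length(feats) == 0) next
    p_set <- union(p_set, table$id[feats])
    pk <- exemplars$peaks[[s]]
    pk <- pk[pk$rel_intensity > min_rel & abs(pk$mz - prec) > ppm * prec, ,
             drop = FALSE]
    if (nrow(pk) == 0) next
    pk <- pk[order(-pk$rel_intensity, pk$mz), , drop = FALSE]
    pk <- pk[seq_len(min(top_k, nrow(pk))), , drop = FALSE]
    for (f in feats) {
      hit <- FALSE
      for (q in seq_len(nrow(pk))) {
        ok <- which(abs(table$mz - pk$mz[q]) <= ppm * pk$mz[q] &
                      abs(table$rt - table$rt[f]) <= w &
                      seq_len(nrow(table)) != f)
        if (length(ok) > 0) { hit <- TRUE; n_frag <- n_frag + 1L }
      }
      if (hit) y_set <- union(y_set, table$id[f])
    }
  }
  list(P = length(p_set), Y = length(y_set), n_frag = n_frag)
}

# exhaustive khipu resolution for one component (<= 8 features):
# anchor = lowest-mz member; cells (isotope index k, modification) with
# offsets from compositions of the mode's isotope-pattern deltas; choose the
# assignment maximizing member count, then minimizing summed |mass error|.
oracle_resolve <- function(feats, mode, ppm = 5e-6, abs_cap = 5e-4) {
  pat <- default_patterns(mode)
  iso <- pat[pat$kind == "isotope", ]
  add <- pat[pat$kind == "adduct", ]
  anchor <- which.min(feats$mz)
  tol <- oracle_tol(feats$mz[anchor], ppm, abs_cap)
  # each composition step consumes one edge of the spanning relation, so at
  # most n - 1 steps; the cumulative delta is also bounded by the m/z span
  max_steps <- nrow(feats) - 1L
  max_cum <- max(feats$mz) - min(feats$mz) + tol

  # all (k, cum) reachable as compositions of isotope steps
  combos <- list(c(k = 0, cum = 0, s = 0))
  frontier <- list(c(k = 0, cum = 0, s = 0))
  while (length(frontier) > 0) {
    nxt <- list()
    for (x in frontier) {
      if (x[["s"]] >= max_steps) next
      for (p in seq_len(nrow(iso))) {
        cum2 <- x[["cum"]] + iso$delta[p]
        if (cum2 > max_cum) next
        nxt[[length(nxt) + 1L]] <- c(k = x[["k"]] + iso$isotope_step[p],
                                     cum = cum2, s = x[["s"]] + 1)
      }
    }
    combos <- c(combos, nxt)
    frontier <- nxt
  }
  combos <- do.call(rbind, combos)
  combos <- unique(combos[, c("k", "cum"), drop = FALSE])

  mods <- rbind(data.frame(mod = "anchor", mdelta = 0),
                data.frame(mod = add$label, mdelta = add$delta))

  # candidate cells per feature
  cands <- lapply(seq_len(nrow(feats)), function(i) {
    out <- list()
    for (ci in seq_len(nrow(combos))) {
      for (mi in seq_len(nrow(mods))) {
        if (i == anchor && !(combos[ci, "k"] == 0 && mods$mod[mi] == "anchor"))
          next
        err <- feats$mz[i] - feats$mz[anchor] - combos[ci, "cum"] -
          mods$mdelta[mi]
        if (abs(err) <= tol) {
          out[[length(out) + 1L]] <- list(
            key = paste(combos[ci, "k"], mods$mod[mi]),
            k = unname(combos[ci, "k"]), mod = mods$mod[mi], err = err
          )
        }
      }
    }
    out
  })

  best <- list(count = -1L, err_sum = Inf, assign = NULL)
  n <- nrow(feats)
  recurse <- function(i, taken, assign, count, err_sum) {
    if (i > n) {
      if (count > best$count ||
          (count == best$count && err_sum < best$err_sum - 1e-12)) {
        best <<- list(count = count, err_sum = err_sum, assign = assign)
      }
      return(invisible())
    }
    for (cand in cands[[i]]) {
      if (cand$key %in% taken) next
      assign[[i]] <- cand
      recurse(i + 1L, c(taken, cand$key), assign, count + 1L,
              err_sum + abs(cand$err))
    }
    assign[i] <- list(NULL)
    recurse(i + 1L, taken, assign, count, err_sum)
  }
  recurse(1L, character(), vector("list", n), 0L, 0)

  a <- best$assign
  if (is.null(a) || is.null(a[[anchor]])) return(NULL)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (is.null(a[[i]])) return(NULL)
    data.frame(feature_id = feats$id[i], isotope_index = a[[i]]$k,
               modification = a[[i]]$mod, stringsAsFactors = FALSE)
  }))
  if (is.null(rows) || nrow(rows) < 2) return(NULL)
  rows[order(rows$feature_id), , drop = FALSE]
}
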