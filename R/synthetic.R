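## Seeded synthetic reaction generator.
##
## Emulates the statistical structure of a curated gas-phase CHNO dataset:
## small molecules (2-7 heavy atoms of C/N/O plus valence-filling hydrogens),
## mostly unimolecular rearrangements (1-3 bond edits), low-level scalars
## drawn from documented distributions, and a ground-truth correction
## Delta_true that is a documented linear function of descriptors the feature
## set can see, plus Gaussian noise. The asymptotic MAE floor of a correct
## model is therefore noise_sd * sqrt(2/pi). Scalars are statistical
## stand-ins, not chemically realistic PES energetics.

#' Generator configuration
#'
#' @param n_reactions number of reactions.
#' @param seed master seed; one seed fixes the whole dataset.
#' @param heavy_atom_range integer range of heavy atoms per molecule
#'   (default 2-7).
#' @param noise_sd Gaussian noise on the correction, kcal/mol (default 2).
#' @param failure_fractions named fractions of planted curation failures
#'   (ts_opt, connectivity, conformation), summing to at most 1.
#' @param correction_coefs named coefficients of the ground-truth linear
#'   correction over (intercept, bh_pm7, eta_ts, lambda1_ts, formed_CH,
#'   broken_CH).
#' @param hidden_driver add a term the feature set cannot see (for studying
#'   graceful degradation); default FALSE.
#' @return A list of class `generatorConfig`.
#' @export
generatorConfig <- function(n_reactions = 100L, seed = 1L,
                            heavy_atom_range = c(2L, 7L), noise_sd = 2,
                            failure_fractions = c(ts_opt = 0,
                                                  connectivity = 0,
                                                  conformation = 0),
                            correction_coefs = c(intercept = -2,
                                                 bh_pm7 = 0.12,
                                                 eta_ts = -1.0,
                                                 lambda1_ts = 1.5,
                                                 formed_CH = 1.2,
                                                 broken_CH = -0.8),
                            hidden_driver = FALSE) {
  stopifnot(noise_sd >= 0, all(failure_fractions >= 0),
            sum(failure_fractions) <= 1,
            length(heavy_atom_range) == 2L,
            heavy_atom_range[1] >= 1L,
            heavy_atom_range[2] >= heavy_atom_range[1])
  structure(list(n_reactions = as.integer(n_reactions),
                 seed = as.integer(seed),
                 heavy_atom_range = as.integer(heavy_atom_range),
                 noise_sd = noise_sd,
                 failure_fractions = failure_fractions,
                 correction_coefs = correction_coefs,
                 hidden_driver = isTRUE(hidden_driver)),
            class = "generatorConfig")
}

## ---- random molecule as an adjacency forest --------------------------------

## Random connected valence-respecting CHNO skeleton with hydrogens filled in.
## Returns symbols and adjacency over all atoms (heavy atoms first).
.randomMolecule <- function(n_heavy) {
  elems <- sample(c("C", "N", "O"), n_heavy, replace = TRUE,
                  prob = c(0.6, 0.2, 0.2))
  val <- .ELEMENTS[elems, "valence"]
  A <- matrix(0, n_heavy, n_heavy)
  if (n_heavy > 1L) {
    for (i in 2:n_heavy) {
      free <- which(rowSums(A)[seq_len(i - 1L)] < val[seq_len(i - 1L)])
      if (length(free) == 0L) free <- seq_len(i - 1L)  # degenerate; rare
      j <- if (length(free) == 1L) free else sample(free, 1L)
      A[i, j] <- A[j, i] <- 1
    }
  }
  n_h <- pmax(val - rowSums(A), 0)
  symbols <- c(elems, rep("H", sum(n_h)))
  n <- length(symbols)
  full <- matrix(0, n, n)
  full[seq_len(n_heavy), seq_len(n_heavy)] <- A
  h_idx <- n_heavy
  for (i in seq_len(n_heavy)) {
    if (n_h[i] > 0) for (k in seq_len(n_h[i])) {
      h_idx <- h_idx + 1L
      full[i, h_idx] <- full[h_idx, i] <- 1
    }
  }
  list(symbols = symbols, adjacency = full, n_heavy = n_heavy)
}

## ---- SMILES writer (acyclic graphs, explicit hydrogen counts) --------------

.graphToSmiles <- function(symbols, A) {
  n <- length(symbols)
  heavy <- which(symbols != "H")
  hcount <- vapply(seq_len(n), function(i) sum(A[i, ] == 1 & symbols == "H"),
                   numeric(1))
  comp <- .components(A)
  frag <- function(atoms) {
    hv <- intersect(atoms, heavy)
    if (length(hv) == 0L) {
      # all-hydrogen fragment (H2 or a lone H atom)
      return(if (length(atoms) == 2L) "[H][H]" else "[H]")
    }
    visited <- logical(n)
    emit <- function(i) {
      visited[i] <<- TRUE
      hc <- hcount[i]
      token <- if (hc > 0)
        paste0("[", symbols[i], "H", if (hc > 1) hc else "", "]")
      else paste0("[", symbols[i], "]")
      kids <- setdiff(intersect(which(A[i, ] == 1), hv), which(visited))
      parts <- vapply(kids, function(k2) emit(k2), "")
      if (length(parts) == 0L) return(token)
      paste0(token,
             paste0(vapply(parts[-length(parts)],
                           function(p) paste0("(", p, ")"), ""),
                    collapse = ""),
             parts[length(parts)])
    }
    emit(hv[1])
  }
  paste(vapply(comp, frag, ""), collapse = ".")
}

## Connected components of an adjacency matrix (list of index vectors).
.components <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  out <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    stack <- s; members <- integer(0)
    while (length(stack) > 0L) {
      i <- stack[[1]]; stack <- stack[-1]
      if (seen[i]) next
      seen[i] <- TRUE; members <- c(members, i)
      stack <- c(stack, which(A[i, ] == 1 & !seen))
    }
    out[[length(out) + 1L]] <- sort(members)
  }
  out
}

## ---- 3D embedding of an acyclic graph --------------------------------------

## Sequentially place atoms so bonded distances are r_cov sums (1 +/- jitter)
## and non-bonded pairs stay beyond margin * threshold. Components are offset
## along x so fragments never interact.
.embedGraph <- function(symbols, A, jitter = 0.03, scale = 1.2,
                        margin = 1.25, max_try = 300L) {
  n <- length(symbols)
  r <- .covalentRadii(symbols)
  coords <- matrix(NA_real_, n, 3)
  comps <- .components(A)
  offset <- 0
  for (comp in comps) {
    order_bfs <- comp
    if (length(comp) > 1L) {
      # BFS order within the component so each atom has a placed parent
      seen <- logical(n); q <- comp[1]; seen[comp[1]] <- TRUE
      order_bfs <- integer(0)
      while (length(q) > 0L) {
        i <- q[[1]]; q <- q[-1]; order_bfs <- c(order_bfs, i)
        nb <- which(A[i, ] == 1 & !seen); seen[nb] <- TRUE; q <- c(q, nb)
      }
    }
    coords[order_bfs[1], ] <- c(offset, 0, 0)
    if (length(order_bfs) > 1L) {
      for (i in order_bfs[-1]) {
        parent <- which(A[i, ] == 1 & !is.na(coords[, 1]))[1]
        d <- (r[i] + r[parent]) * (1 + stats::runif(1, -jitter, jitter))
        placed <- setdiff(which(!is.na(coords[, 1])), i)
        ok <- FALSE
        for (tr in seq_len(max_try)) {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          pos <- coords[parent, ] + d * u
          others <- setdiff(placed, parent)
          if (length(others) == 0L) { ok <- TRUE; break }
          dd <- sqrt(colSums((t(coords[others, , drop = FALSE]) - pos)^2))
          lim <- scale * (r[i] + r[others]) * margin
          if (all(dd > lim)) { ok <- TRUE; break }
        }
        if (!ok) return(NULL)  # caller retries with fresh randomness
        coords[i, ] <- pos
      }
    }
    offset <- offset + 12  # well-separated fragments
  }
  coords
}

.embedOrRetry <- function(symbols, A, ...) {
  for (k in seq_len(50L)) {
    coords <- .embedGraph(symbols, A, ...)
    if (!is.null(coords)) return(coords)
  }
  stop("embedding failed repeatedly; graph too crowded", call. = FALSE)
}

## ---- species-level scalars --------------------------------------------------

.randomScalars <- function(symbols, A, is_ts = FALSE) {
  n <- length(symbols)
  n_modes <- max(1L, 3L * n - 6L)
  freqs <- sort(stats::runif(n_modes, 300, 3200))
  if (is_ts) freqs[1] <- -stats::runif(1, 400, 2000)
  zpe_val <- sum(freqs[freqs > 0]) / 2 * .CONST$cm1_to_kcal
  homo <- stats::rnorm(1, -9.5, 0.8)
  lumo <- homo + stats::runif(1, 2, 8)
  B <- A * matrix(stats::runif(n * n, 0.9, 1.1), n, n)
  B <- (B + t(B)) / 2
  diag(B) <- rowSums(A) * stats::runif(n, 0.95, 1.05)
  list(freqs = freqs, zpe = zpe_val, homo = homo, lumo = lumo, B = B,
       pol = 0.55 * n + stats::rnorm(1, 0, 0.3))
}

## ---- reaction edits ---------------------------------------------------------

## Apply one random valence-preserving edit to (symbols, A); returns new A or
## NULL if no move of the drawn type applies.
.randomEdit <- function(symbols, A) {
  val <- .ELEMENTS[symbols, "valence"]
  deg <- rowSums(A)
  heavy <- which(symbols != "H")
  hyd <- which(symbols == "H")
  moves <- sample(c("h_migration", "heavy_migration", "h2_elimination"))
  for (mv in moves) {
    if (mv == "h_migration") {
      hs <- hyd[deg[hyd] == 1]
      if (length(hs) == 0L) next
      h <- if (length(hs) == 1L) hs else sample(hs, 1L)
      a <- which(A[h, ] == 1)
      b_cand <- setdiff(heavy[deg[heavy] < val[heavy]], a)
      if (length(b_cand) == 0L) next
      b <- if (length(b_cand) == 1L) b_cand else sample(b_cand, 1L)
      A[h, a] <- A[a, h] <- 0
      A[h, b] <- A[b, h] <- 1
      return(A)
    }
    if (mv == "heavy_migration") {
      term <- heavy[deg[heavy] - vapply(heavy, function(i)
        sum(A[i, hyd]), numeric(1)) == 1L]  # one heavy neighbor
      if (length(term) == 0L) next
      t_at <- if (length(term) == 1L) term else sample(term, 1L)
      a <- intersect(which(A[t_at, ] == 1), heavy)[1]
      b_cand <- setdiff(heavy[deg[heavy] < val[heavy]], c(a, t_at))
      if (length(b_cand) == 0L) next
      b <- if (length(b_cand) == 1L) b_cand else sample(b_cand, 1L)
      A[t_at, a] <- A[a, t_at] <- 0
      A[t_at, b] <- A[b, t_at] <- 1
      return(A)
    }
    if (mv == "h2_elimination") {
      hs <- hyd[deg[hyd] == 1 & vapply(hyd, function(h)
        any(A[h, heavy] == 1), logical(1))]
      if (length(hs) < 2L) next
      pick <- sample(hs, 2L)
      a1 <- which(A[pick[1], ] == 1); a2 <- which(A[pick[2], ] == 1)
      if (length(a1) != 1L || length(a2) != 1L || a1 == a2) next
      A[pick[1], a1] <- A[a1, pick[1]] <- 0
      A[pick[2], a2] <- A[a2, pick[2]] <- 0
      A[pick[1], pick[2]] <- A[pick[2], pick[1]] <- 1
      return(A)
    }
  }
  NULL
}

## ---- public generator operations -------------------------------------------

#' Generate one random species
#'
#' Valence-respecting connected CHNO molecule with an embedded 3D geometry
#' (bonded distances equal to covalent-radius sums with small jitter,
#' non-bonded pairs well separated) and randomized low-level scalars.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param seed seed for this draw (default: the config seed).
#' @return List with `geometry`, `graph` (the intended
#'   \linkS4class{MolecularGraph}), `species` (\linkS4class{SQMSpecies}) and
#'   `smiles`.
#' @export
genSpecies <- function(cfg, seed = cfg$seed) {
  .withSeed(seed, {
    n_heavy <- sample(seq(cfg$heavy_atom_range[1], cfg$heavy_atom_range[2]),
                      1L)
    mol <- .randomMolecule(n_heavy)
    coords <- .embedOrRetry(mol$symbols, mol$adjacency)
    geom <- Geometry(mol$symbols, coords)
    sc <- .randomScalars(mol$symbols, mol$adjacency)
    sp <- SQMSpecies(energy = stats::rnorm(1, 0, 20), zpe = sc$zpe,
                     frequencies = sc$freqs, homo = sc$homo, lumo = sc$lumo,
                     bondOrders = sc$B, selfPolarizability = sc$pol,
                     geometry = geom)
    list(geometry = geom,
         graph = new("MolecularGraph", adjacency = mol$adjacency,
                     atomicNumbers = as.integer(.atomicNumbers(mol$symbols))),
         species = sp,
         smiles = .graphToSmiles(mol$symbols, mol$adjacency))
  })
}

#' Generate one reaction with known ground truth
#'
#' Product = reactant graph after 1-3 valence-preserving bond edits
#' (hydrogen migration, heavy-group migration, H2 elimination); the TS
#' geometry is the reactant geometry with the breaking bonds stretched
#' toward the product (a stand-in for a point along the reaction path) and
#' carries exactly one planted imaginary frequency. The true correction is
#' `Delta_true = c0 + c1 BH_PM7 + c2 eta_TS + c3 lambda1_TS + c4 (+CH) +
#' c5 (-CH) + N(0, noise_sd^2)` with the coefficients from the config, and
#' `BH_DFT = BH_PM7 + Delta_true`.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param seed seed for this draw.
#' @param planted_failure one of "none", "ts_opt", "connectivity",
#'   "conformation": which curation failure, if any, to plant in the raw
#'   record.
#' @return List with `record` (\linkS4class{ReactionRecord}), `raw`
#'   (\linkS4class{RawRecord}), `delta_true` and `planted_failure`.
#' @export
genReaction <- function(cfg, seed = cfg$seed, planted_failure = "none") {
  .withSeed(seed, {
    repeat {
      n_heavy <- sample(seq(max(2L, cfg$heavy_atom_range[1]),
                            cfg$heavy_atom_range[2]), 1L)
      mol <- .randomMolecule(n_heavy)
      n_edits <- sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
      Ap <- mol$adjacency
      done <- 0L
      for (e in seq_len(n_edits)) {
        Anew <- .randomEdit(mol$symbols, Ap)
        if (is.null(Anew)) break
        Ap <- Anew; done <- done + 1L
      }
      if (done >= 1L && !identical(Ap, mol$adjacency)) break
    }
    symbols <- mol$symbols
    Ar <- mol$adjacency
    z <- as.integer(.atomicNumbers(symbols))
    gR <- new("MolecularGraph", adjacency = Ar, atomicNumbers = z)
    gP <- new("MolecularGraph", adjacency = Ap, atomicNumbers = z)

    coords_r <- .embedOrRetry(symbols, Ar)
    coords_p <- .embedOrRetry(symbols, Ap)
    geom_r <- Geometry(symbols, coords_r)
    geom_p <- Geometry(symbols, coords_p)

    # TS geometry: stretch the breaking bonds by moving the smaller side of
    # each broken edge outward along the bond direction
    coords_ts <- coords_r
    broken <- which(upper.tri(Ar) & Ar == 1 & Ap == 0, arr.ind = TRUE)
    if (nrow(broken) > 0L) {
      for (k in seq_len(nrow(broken))) {
        i <- broken[k, 1]; j <- broken[k, 2]
        # move atom j (and nothing else: leaves in acyclic graphs are safe
        # to displace slightly) 12% along the bond
        vec <- coords_ts[j, ] - coords_ts[i, ]
        coords_ts[j, ] <- coords_ts[i, ] + vec * 1.12
      }
    }
    coords_ts <- coords_ts + matrix(stats::rnorm(length(coords_ts), 0, 0.005),
                                    ncol = 3)
    geom_ts <- Geometry(symbols, coords_ts)

    sc_r <- .randomScalars(symbols, Ar)
    sc_p <- .randomScalars(symbols, Ap)
    sc_t <- .randomScalars(symbols, Ar, is_ts = TRUE)

    bh_pm7 <- 5 + stats::rgamma(1, shape = 4, scale = 8)
    e_r <- stats::rnorm(1, 0, 20)
    e_ts <- e_r + bh_pm7 - (sc_t$zpe - sc_r$zpe)
    e_p <- e_r + stats::rnorm(1, 0, 15)

    reactant <- SQMSpecies(e_r, sc_r$zpe, sc_r$freqs, sc_r$homo, sc_r$lumo,
                           sc_r$B, sc_r$pol, geom_r)
    tsp <- SQMSpecies(e_ts, sc_t$zpe, sc_t$freqs, sc_t$homo, sc_t$lumo,
                      sc_t$B, sc_t$pol, geom_ts)
    product <- SQMSpecies(e_p, sc_p$zpe, sc_p$freqs, sc_p$homo, sc_p$lumo,
                          sc_p$B, sc_p$pol, geom_p)

    # ground-truth correction from descriptors the feature set can see
    cf <- cfg$correction_coefs
    eta_ts <- unname(koopmans(sc_t$homo, sc_t$lumo)["eta"])
    lambda1 <- spectralGap(weightedGraph(geom_ts))
    bc <- bondChanges(gR, gP)
    delta_det <- cf["intercept"] + cf["bh_pm7"] * bh_pm7 +
      cf["eta_ts"] * eta_ts + cf["lambda1_ts"] * lambda1 +
      cf["formed_CH"] * bc["bonds.+CH"] + cf["broken_CH"] * bc["bonds.-CH"]
    if (cfg$hidden_driver) delta_det <- delta_det + stats::rnorm(1, 0, 3)
    delta_true <- unname(delta_det) +
      stats::rnorm(1, 0, cfg$noise_sd)
    bh_dft <- bh_pm7 + delta_true

    id <- sprintf("rxn%09d", seed %% 1000000000L)
    record <- ReactionRecord(id, reactant, tsp, product, bh_dft,
                             .graphToSmiles(symbols, Ar),
                             .graphToSmiles(symbols, Ap))

    # raw record for the curation flow, optionally with a planted failure
    irc_f <- geom_r; irc_v <- geom_p
    opt_f <- geom_r; opt_v <- geom_p
    if (stats::runif(1) < 0.5) {  # exercise the direction logic
      tmp <- irc_f; irc_f <- irc_v; irc_v <- tmp
      tmp <- opt_f; opt_f <- opt_v; opt_v <- tmp
    }
    ts_ok <- TRUE
    if (planted_failure == "ts_opt") ts_ok <- FALSE
    if (planted_failure == "connectivity") { irc_f <- geom_p; irc_v <- geom_p }
    if (planted_failure == "conformation") {
      opt_f <- .stretchOneBond(opt_f, 1.10)
      opt_v <- .stretchOneBond(opt_v, 1.10)
    }
    raw <- RawRecord(id, geom_r, geom_p, ts_ok, irc_f, irc_v, opt_f, opt_v,
                     geom_r, geom_p)
    list(record = record, raw = raw, delta_true = delta_true,
         planted_failure = planted_failure)
  })
}

## Stretch the first bond of a geometry by `factor` (moving one endpoint);
## keeps connectivity at the default scale but shifts the weighted spectrum.
.stretchOneBond <- function(geom, factor = 1.10) {
  g <- buildGraph(geom)
  e <- which(upper.tri(g@adjacency) & g@adjacency == 1, arr.ind = TRUE)
  if (nrow(e) == 0L) return(geom)
  i <- e[1, 1]; j <- e[1, 2]
  coords <- geom@coords
  coords[j, ] <- coords[i, ] + (coords[j, ] - coords[i, ]) * factor
  Geometry(geom@symbols, coords)
}

#' Generate a full synthetic dataset
#'
#' Draws `cfg$n_reactions` reactions with per-record child seeds derived from
#' the master seed, planting curation failures according to
#' `cfg$failure_fractions` (deterministic counts: `round(fraction * n)`,
#' positions seeded).
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @return List with `records`, `raw_records`, `delta_true`,
#'   `planted` (character vector of planted failure labels) and `cfg`.
#' @export
genDataset <- function(cfg) {
  n <- cfg$n_reactions
  ff <- cfg$failure_fractions
  n_ts <- round(ff[["ts_opt"]] * n)
  n_conn <- round(ff[["connectivity"]] * n)
  n_conf <- round(ff[["conformation"]] * n)
  planted <- rep("none", n)
  pos <- .withSeed(.childSeed(cfg$seed, 1L), sample.int(n))
  planted[pos[seq_len(n_ts)]] <- "ts_opt"
  planted[pos[n_ts + seq_len(n_conn)]] <- "connectivity"
  planted[pos[n_ts + n_conn + seq_len(n_conf)]] <- "conformation"
  out <- lapply(seq_len(n), function(i)
    genReaction(cfg, seed = .childSeed(cfg$seed, 100L + i),
                planted_failure = planted[i]))
  list(records = lapply(out, `[[`, "record"),
       raw_records = lapply(out, `[[`, "raw"),
       delta_true = vapply(out, `[[`, numeric(1), "delta_true"),
       planted = planted,
       cfg = cfg)
}
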