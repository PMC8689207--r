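# Shared fixtures built in code at test time.

# a bare-bones atoms data.frame row
atom_row <- function(element, name, resname, chain, resno, x, y, z,
                     b = 20, occ = 1) {
  data.frame(element = element, name = name, residue_name = resname,
             chain_id = chain, residue_number = resno, x = x, y = y, z = z,
             b_factor = b, occupancy = occ, stringsAsFactors = FALSE)
}

# append extra atoms (data.frame) to a structure_model
model_with <- function(model, extra) {
  structure_model(rbind(model$atoms, extra), source_id = model$source_id)
}

# a single chl site object from a fixture model
fixture_site <- function(chl_type = "a", site_name = "S1", ...) {
  fx <- make_chl_fixture(chl_type, ...)
  tb <- data.frame(chain = fx$atoms$chain_id[1],
                   resnum = fx$atoms$residue_number[1],
                   site_name = site_name)
  extract_chl_sites(fx, tb)[[1]]
}

# rescaled map that is exactly zero in a central region: two compensating
# spikes in one corner make mean 0 / sd 1 legitimate without touching the
# region of interest
zero_region_map <- function(dim = c(40, 40, 40), voxel = 0.8,
                            origin = -c(16, 16, 16)) {
  g <- array(0, dim)
  n <- prod(dim)
  a <- sqrt(n / 2)          # two spikes +/- a give mean 0, pop sd 1
  g[1, 1, 1] <- a
  g[2, 1, 1] <- -a
  esp_map(g, voxel, origin, rescaled = TRUE)
}

# independent brute-force trilinear interpolation (scalar, loop form)
brute_trilinear <- function(map, p) {
  f <- (p - map$origin) / map$voxel_size
  i <- floor(f); w <- f - i
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[1] else 1 - w[1]) *
          (if (dy) w[2] else 1 - w[2]) *
          (if (dz) w[3] else 1 - w[3])
    acc <- acc + wt * map$grid[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1]
  }
  acc
}

# independent Needleman-Wunsch global alignment score (affine gaps,
# open+extend charged as open on first gap position), BLOSUM62
nw_score <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # match state
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (a aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  # Biostrings convention: a gap of length L costs gap_open + L * gap_extend
  open1 <- gap_open + gap_extend
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_extend
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open1, X[i - 1, j] - gap_extend,
                   Y[i - 1, j] - open1)
    Y[i, j] <- max(M[i, j - 1] - open1, Y[i, j - 1] - gap_extend,
                   X[i, j - 1] - open1)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_aa <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
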