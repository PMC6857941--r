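# Brute-force oracles, independent of the package internals: connectivity,
# hydroxyl detection and hydroxyl-midpoint distances are recomputed here by
# direct double loops over atom pairs with a locally defined radius table.

oracle_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07,
                  S = 1.05, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39)

oracle_neighbors <- function(atoms, scale = 1.2) {
  n <- nrow(atoms)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((atoms$x[i] - atoms$x[j])^2 +
                (atoms$y[i] - atoms$y[j])^2 +
                (atoms$z[i] - atoms$z[j])^2)
      lim <- scale * (oracle_radii[[toupper(atoms$element[i])]] +
                      oracle_radii[[toupper(atoms$element[j])]])
      if (d <= lim && d > 0.01) nb[[i]] <- c(nb[[i]], j)
    }
  }
  nb
}

oracle_hydroxyls <- function(atoms) {
  nb <- oracle_neighbors(atoms)
  el <- toupper(atoms$element)
  any_h <- any(el == "H")
  out <- integer(0)
  for (i in which(el == "O")) {
    nel <- el[nb[[i]]]
    ok <- if (any_h) {
      sum(nel == "C") == 1 && sum(nel == "H") == 1 && length(nel) == 2
    } else {
      length(nel) == 1 && nel == "C"
    }
    if (ok) out <- c(out, i)
  }
  out
}

oracle_min_hydroxyl_dist <- function(atoms, midpoint) {
  ox <- oracle_hydroxyls(atoms)
  min(vapply(ox, function(i) {
    sqrt(sum((c(atoms$x[i], atoms$y[i], atoms$z[i]) - midpoint)^2))
  }, numeric(1)))
}

# a fixed proper rotation matrix (QR of a seeded random matrix)
oracle_rotation <- function(seed = 424242) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# bare reference object when only a midpoint is needed
midpoint_reference <- function(midpoint) {
  structure(list(carbon_index = NA_integer_, oxygen_index = NA_integer_,
                 midpoint = midpoint),
            class = "glycosidic_reference")
}

make_atoms <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], element = r[[2]],
               x = as.numeric(r[[3]]), y = as.numeric(r[[4]]),
               z = as.numeric(r[[5]]), stringsAsFactors = FALSE)
  }))
}
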