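#' Construct a spherical sensor montage with neighbor structure
#'
#' Places `n_sensors` electrodes quasi-uniformly (Fibonacci lattice) on the
#' upper portion of a unit sphere, emulating the coverage of a high-density
#' geodesic net, and derives a symmetric adjacency from nearest neighbors.
#' Every sensor is guaranteed at least `min_neighbors` neighbors, which is
#' what neighbor-average bad-sensor repair requires.
#'
#' @param n_sensors Number of electrodes (default 128).
#' @param min_neighbors Minimum neighbors per sensor (default 6).
#' @param z_min Lowest z-coordinate covered by the net; the default leaves
#'   the bottom of the sphere (neck/face) bare as real nets do.
#' @return An object of class `ssvep_montage`: `n_sensors`, `positions`
#'   (n x 3 matrix, unit radius), `adjacency` (list of integer vectors,
#'   ordered by increasing distance).
#' @examples
#' mon <- make_montage(128)
#' range(lengths(mon$adjacency))  # all >= 6
#' @export
make_montage <- function(n_sensors = 128L, min_neighbors = 6L, z_min = -0.25) {
  stopifnot(n_sensors >= min_neighbors + 1L, min_neighbors >= 1L)
  n <- as.integer(n_sensors)
  i <- seq_len(n) - 0.5
  z <- z_min + (1 - z_min) * (i / n)         # even spacing in z over the cap
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (seq_len(n) - 1L)
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  d <- as.matrix(stats::dist(pos))
  adjacency <- vector("list", n)
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    adjacency[[s]] <- ord[ord != s][seq_len(min_neighbors)]
  }
  # symmetrize: if s lists t, t must list s (append, keep distance order)
  for (s in seq_len(n)) {
    for (t in adjacency[[s]]) {
      if (!(s %in% adjacency[[t]])) {
        nb <- c(adjacency[[t]], s)
        adjacency[[t]] <- nb[order(d[t, nb])]
      }
    }
  }
  structure(list(n_sensors = n, positions = pos, adjacency = adjacency),
            class = "ssvep_montage")
}

#' @export
print.ssvep_montage <- function(x, ...) {
  cat(sprintf("SSVEP montage: %d sensors, %d-%d neighbors per sensor\n",
              x$n_sensors, min(lengths(x$adjacency)),
              max(lengths(x$adjacency))))
  invisible(x)
}

#' Write a montage to a plain-text sidecar file
#'
#' One row per sensor: id, x, y, z, and a `;`-separated neighbor list.
#'
#' @param montage An `ssvep_montage`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(
    sensor = seq_len(montage$n_sensors),
    x = montage$positions[, 1], y = montage$positions[, 2],
    z = montage$positions[, 3],
    neighbors = vapply(montage$adjacency, paste, "", collapse = ";"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
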