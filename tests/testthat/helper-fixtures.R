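# shared fixtures and small oracles, built in code

toy7_lines <- function() c(
  "# soil_ref=1",
  "0 stem -5.0 0.0 0.0",
  "1 stem 0.0 0.0 0.0",
  "2 stem 20.0 0.0 0.0",
  "2.1 root 20.0 0.0 0.0",
  "2.2 root 25.0 4.0 3.0",
  "2.2.1 root 25.0 4.0 3.0",
  "2.2.2 root 33.0 4.0 3.0")

# mean of a normal truncated to positive values (resample-until-positive
# sampling draws from exactly this distribution)
truncnorm_mean <- function(mu, sd) {
  if (sd == 0) return(mu)
  mu + sd * stats::dnorm(mu / sd) / stats::pnorm(mu / sd)
}

# simple single-axis root systems for trait/hydraulic tests
vertical_axis_system <- function(length_cm = 10, radius = 0.1, n = 11,
                                 type = 2L, age = 100) {
  z <- seq(0, -length_cm, length.out = n)
  root_system(list(root_axis(cbind(0, 0, z), type = type,
                             ages = rep(age, n), radius = radius)))
}

# random branched root system (stem + type-1 + type-2), used for
# property-style tests; geometry is arbitrary but valid
random_root_system <- function(seed, n_type1 = 3, n_type2 = 2) {
  set.seed(seed)
  stem <- root_axis(cbind(0, 0, seq(2, -15, length.out = n_type1 + 2)),
                    type = 0L, radius = 0.5, ages = rep(400, n_type1 + 2))
  axes <- list(stem)
  for (k in seq_len(n_type1)) {
    jp <- k + 2L
    dirv <- c(stats::rnorm(2), -abs(stats::rnorm(1)) - 0.3)
    dirv <- dirv / sqrt(sum(dirv^2))
    n <- 6L
    s <- seq(0, stats::runif(1, 8, 16), length.out = n)
    nodes <- sweep(outer(s, dirv), 2, stem$nodes[jp, ], "+")
    nodes[1, ] <- stem$nodes[jp, ]
    axes[[length(axes) + 1L]] <- root_axis(
      nodes, type = 1L, radius = 0.2, ages = rep(400, n),
      parent = 1L, parent_node = jp)
    t1 <- length(axes)
    for (m in seq_len(n_type2)) {
      jj <- 1L + m
      d2 <- c(stats::rnorm(2), -abs(stats::rnorm(1)))
      d2 <- d2 / sqrt(sum(d2^2))
      s2 <- seq(0, stats::runif(1, 5, 25), length.out = 5)
      nd <- sweep(outer(s2, d2), 2, nodes[jj, ], "+")
      nd[1, ] <- nodes[jj, ]
      axes[[length(axes) + 1L]] <- root_axis(
        nd, type = 2L, radius = 0.1, ages = rep(stats::runif(1, 5, 150), 5),
        parent = t1, parent_node = jj)
    }
  }
  root_system(axes)
}

# rotate a root system about the vertical axis (traits must be invariant)
rotate_root_system <- function(rs, angle) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  rs$axes <- lapply(rs$axes, function(a) {
    a$nodes <- a$nodes %*% R
    a
  })
  rs
}

# independent depth-binning oracle: chop segments into tiny pieces and
# accumulate their length into bins
depth_bins_oracle <- function(rs, h, step = 0.01) {
  acc <- new.env(parent = emptyenv())
  for (a in rs$axes) {
    if (a$type == 0L) next
    nd <- a$nodes
    for (k in seq_len(nrow(nd) - 1L)) {
      p <- nd[k, ]; q <- nd[k + 1L, ]
      len <- sqrt(sum((q - p)^2))
      n <- max(2L, ceiling(len / step))
      t_mid <- (seq_len(n) - 0.5) / n
      piece <- len / n
      depth_mid <- -(p[3] + t_mid * (q[3] - p[3]))
      for (d in depth_mid) {
        key <- as.character(floor(d / h))
        assign(key, get0(key, envir = acc, ifnotfound = 0) + piece,
               envir = acc)
      }
    }
  }
  keys <- as.integer(ls(acc))
  data.frame(bin = sort(keys),
             length = vapply(as.character(sort(keys)),
                             function(k) get(k, envir = acc), numeric(1)))
}
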