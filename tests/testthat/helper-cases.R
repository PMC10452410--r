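## Shared fixtures, all generated in code.

## Memoized three-topography experiment on the coarse scaled implant
## domain; run once per test session and reused by the acceptance tests.
.periflow_cache <- new.env(parent = emptyenv())

mini_runs <- function() {
  if (!is.null(.periflow_cache$runs)) return(.periflow_cache$runs)
  runs <- list()
  for (topo in c("amorphous", "nano", "hybrid")) {
    cs <- periflow:::mini_implant_case(30, topo, end_time = 3)
    runs[[topo]] <- run_simulation(cs$geom, cs$props, cs$config,
                                   boundaries = cs$boundaries)
    runs[[topo]]$geom_case <- cs$geom
  }
  .periflow_cache$runs <- runs
  runs
}

## A tiny all-fluid square domain with hand-assigned zones.
tiny_zoned_domain <- function(n = 4, h_um = 100) {
  geom <- rasterize_domain(NULL, h = h_um,
                           domain_mm = c(n * h_um / 1000, n * h_um / 1000))
  zone <- matrix(periflow:::ZN_OUTER, geom$nx, geom$ny)
  zone[1:2, ] <- periflow:::ZN_INTERFACE
  zone[3, ] <- periflow:::ZN_THREAD
  geom$zone <- zone
  geom
}

## Flow state with prescribed fields on a given geometry.
state_with <- function(geom, alpha = 1, u = 0, v = 0, c = 0) {
  st <- initialize_state(geom, fluid_properties(), solver_config())
  st$alpha[] <- alpha
  st$alpha[geom$type != 0L] <- 0
  st$u[] <- u
  st$v[] <- v
  st$m <- st$alpha * c
  st$c <- st$m
  st
}

## Independent all-pairs proper-intersection oracle for closed polylines.
brute_force_self_intersects <- function(xy) {
  n <- nrow(xy)
  seg <- cbind(xy, xy[c(2:n, 1), ])
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (a in 1:(n - 1)) {
    for (b in (a + 1):n) {
      if (abs(a - b) <= 1 || (a == 1 && b == n)) next
      p1 <- seg[a, 1:2]; p2 <- seg[a, 3:4]
      q1 <- seg[b, 1:2]; q2 <- seg[b, 3:4]
      d1 <- cross2(p2[1] - p1[1], p2[2] - p1[2], q1[1] - p1[1], q1[2] - p1[2])
      d2 <- cross2(p2[1] - p1[1], p2[2] - p1[2], q2[1] - p1[1], q2[2] - p1[2])
      d3 <- cross2(q2[1] - q1[1], q2[2] - q1[2], p1[1] - q1[1], p1[2] - q1[2])
      d4 <- cross2(q2[1] - q1[1], q2[2] - q1[2], p2[1] - q1[1], p2[2] - q1[2])
      if (d1 * d2 < -1e-12 && d3 * d4 < -1e-12) return(TRUE)
    }
  }
  FALSE
}
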