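# Shared fixtures and independent oracles, all built in code.

# CognitiveProfile straight from a named z vector (bypasses raw scoring).
make_profile <- function(z, id = "T") {
  tz <- stats::setNames(rep(0, 10), batteryTests())
  tz[names(z)] <- z
  layout <- batteryLayout()
  new("CognitiveProfile", subjectId = id, testZ = tz,
      domainZ = vapply(batteryDomains(),
                       function(d) mean(tz[layout == d]), numeric(1)),
      overallZ = mean(tz))
}

# Brute-force Level II oracle: enumerate the impaired-test subset directly.
oracle_classify <- function(tz, threshold = 1.5) {
  layout <- batteryLayout()
  impaired <- names(tz)[tz <= -threshold]
  doms <- unique(unname(layout[impaired]))
  status <- if (length(impaired) >= 2) "MCI" else "NC"
  subtype <- if (status == "NC") "none"
             else if (length(doms) == 1) "single_domain"
             else "multiple_domain"
  list(status = status, subtype = subtype,
       amnestic = status == "MCI" && "memory" %in% doms)
}

# Exact Mann-Whitney U (and two-sided p) by exhaustive enumeration of all
# rank assignments; feasible only for tiny samples.
oracle_u_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * n2 / 2
  # two-sided: as extreme in either direction
  p <- mean(abs(us - mu) >= abs(u_obs - mu))
  list(U = u_obs, p = p)
}

# Pure-R flood fill (6/18/26 connectivity) as an independent oracle for
# the C++ component labeller.
oracle_flood_fill <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(offs))
  offs <- offs[s > 0 & s <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  labels <- array(0L, dim = d)
  cur <- 0L
  for (v in which(mask)) {
    if (labels[v] != 0L) next
    cur <- cur + 1L
    queue <- list(arrayInd(v, d))
    labels[v] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && labels[q[1], q[2], q[3]] == 0L) {
          labels[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  labels
}

# Tiny volume stack with fully specified data for exact checks.
make_stack <- function(data, grid, voxel_size = 4,
                       ids = sprintf("S%02d", seq_len(nrow(data)))) {
  new("VolumeStack", data = data, grid = as.integer(grid),
      affine = isacog:::defaultAffine(as.integer(grid), voxel_size),
      mask = array(TRUE, dim = grid), subjectIds = ids)
}

# Random covariate table for imaging designs.
make_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("P%03d", seq_len(n)),
             isacog_magnitude = rnorm(n), age = runif(n, 55, 80),
             sex = sample(c("male", "female"), n, TRUE),
             bdi2 = pmax(0, rnorm(n, 9, 4)),
             updrs3 = pmax(0, rnorm(n, 30, 10)),
             ledd = pmax(0, rnorm(n, 650, 250)),
             stringsAsFactors = FALSE)
}

# Raw-score fixture: build a subject row whose z-scores (via `norms`)
# equal the requested named z vector.
make_subject_raw <- function(z, norms, id = "X01", age = 65,
                             education = 12) {
  row <- list(subject_id = id, age = age, education = education)
  e <- norms@entries
  for (tt in batteryTests()) {
    ent <- e[e$test == tt, ]
    mu <- ent$intercept + ent$age_slope * age + ent$edu_slope * education
    zz <- if (tt %in% names(z)) z[[tt]] else 0
    row[[tt]] <- if (ent$direction == "higher_is_worse")
      mu - zz * ent$sd else mu + zz * ent$sd
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

full_norms <- function() {
  mergeNormTables(defaultNormTable(),
                  normTable(isacog:::control_reference_truth()))
}
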