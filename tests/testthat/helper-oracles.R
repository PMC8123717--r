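# Independent oracles and fixture builders, coded separately from the
# package implementation paths they check.

# A single fully specified respondent; override any field.
make_record <- function(...) {
  base <- list(
    person_id = "P1", country = "ES", weight = 1000, gender = "female",
    age_years = 65L, marital_status = "with_partner",
    education_years = "12", hh_income = 20000, n_adults = 2L,
    n_children = 0L, job_situation = "retired", isco = NA_character_,
    fdistress = 4L, legeggs = 3L, meat = 3L, sphus = "good", chronic = 0L,
    eurod = 2L, lifesat = 8L, lifehap = "often", gali = "not_limited",
    mobility = 0L, adl = 0L, iadl = 0L, bmi = 22.0, doctor_visits = 3L,
    hospital_nights = 0L)
  ov <- list(...)
  base[names(ov)] <- ov
  as.data.frame(base, stringsAsFactors = FALSE)
}

make_records <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, rows)
  df$person_id <- sprintf("P%d", seq_len(nrow(df)))
  df
}

toy_thresholds <- function(countries = "ES", value = 10000) {
  data.frame(country = countries, threshold_eur = rep(value, length(countries)),
             stringsAsFactors = FALSE)
}

# Rule oracle: per-row scalar re-derivation of every subindicator with an
# explicit, unvectorised coding of each published binarization rule.
rule_oracle_row <- function(r, threshold) {
  eq <- r$hh_income / (1 + 0.5 * (r$n_adults - 1) + 0.3 * r$n_children)
  pov <- if (eq < threshold) 1L else 0L
  unemp <- if (r$job_situation == "unemployed") 1L else 0L
  dist <- if (r$fdistress == 1 || r$fdistress == 2) 1L else 0L
  cons <- if ((r$legeggs + r$meat) <= 2) 1L else 0L
  gh <- 0L
  if (r$sphus == "fair" || r$sphus == "poor" || r$sphus == "very_poor") gh <- gh + 1L
  if (r$chronic >= 2) gh <- gh + 1L
  mh <- 0L
  if (r$eurod > 4) mh <- mh + 1L
  if (r$lifesat <= 6) mh <- mh + 1L
  if (r$lifehap == "rarely" || r$lifehap == "never") mh <- mh + 1L
  ph <- 0L
  if (r$gali == "limited") ph <- ph + 1L
  if (r$mobility > 0) ph <- ph + 1L
  if (r$adl > 0) ph <- ph + 1L
  if (r$iadl > 0) ph <- ph + 1L
  if (r$bmi < 18.5) ph <- ph + 1L else if (r$bmi >= 25.0) ph <- ph + 1L
  hc <- 0L
  if (r$doctor_visits == 0) hc <- hc + 1L else if (r$doctor_visits >= 52) hc <- hc + 1L
  if (r$hospital_nights >= 1) hc <- hc + 1L
  e_raw <- pov + unemp + dist + cons
  h_raw <- gh + mh + ph + hc
  c(monetary_poverty = pov, unemployment = unemp, financial_distress = dist,
    weekly_consumption = cons, general_health = gh, mental_health = mh,
    physical_health = ph, health_care = hc,
    economic_raw = e_raw, health_raw = h_raw,
    economic_indicator = e_raw * 2.5, health_indicator = h_raw * 10 / 12)
}

# Reference *unweighted* k-prototypes: plain alternating loop with
# unweighted means and plain-count modes (lexicographic ties), used as
# the independent implementation for the equal-weights reduction check.
kproto_reference <- function(Xn, Xc, k, lambda, init_idx, max_iter = 100) {
  n <- nrow(Xn)
  centers <- Xn[init_idx, , drop = FALSE]
  modes <- Xc[init_idx, , drop = FALSE]
  assign_old <- rep(0L, n)
  for (iter in 1:max_iter) {
    D <- matrix(0, n, k)
    for (j in 1:k) {
      for (i in 1:n) {
        d <- sum((Xn[i, ] - centers[j, ])^2)
        if (ncol(Xc) > 0) d <- d + lambda * sum(Xc[i, ] != modes[j, ])
        D[i, j] <- d
      }
    }
    assign <- apply(D, 1, which.min)
    if (all(assign == assign_old)) break
    for (j in 1:k) {
      idx <- which(assign == j)
      if (length(idx) == 0) next
      centers[j, ] <- colMeans(Xn[idx, , drop = FALSE])
      if (ncol(Xc) > 0) {
        for (v in 1:ncol(Xc)) {
          tab <- table(Xc[idx, v])
          modes[j, v] <- names(tab)[which.max(tab)]  # table() sorts names
        }
      }
    }
    assign_old <- assign
  }
  cost <- sum(D[cbind(1:n, assign)])
  list(assign = assign, centers = centers, modes = modes, cost = cost)
}

# Exhaustive global minimum of the weighted k-prototypes cost for k = 2:
# enumerate every bipartition, place optimal prototypes (weighted mean /
# weighted mode with lexicographic ties) in each block, take the minimum.
exhaustive_k2_cost <- function(Xn, Xc, w, lambda) {
  n <- nrow(Xn)
  stopifnot(n <= 10)
  block_cost <- function(idx) {
    wi <- w[idx]
    cost <- 0
    for (v in seq_len(ncol(Xn))) {
      mu <- sum(wi * Xn[idx, v]) / sum(wi)
      cost <- cost + sum(wi * (Xn[idx, v] - mu)^2)
    }
    for (v in seq_len(ncol(Xc))) {
      lev <- sort(unique(Xc[idx, v]))
      s <- sapply(lev, function(l) sum(wi[Xc[idx, v] == l]))
      cost <- cost + lambda * (sum(wi) - max(s))
    }
    cost
  }
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    inA <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    a <- which(inA); b <- which(!inA)
    if (length(a) == 0 || length(b) == 0) next
    best <- min(best, block_cost(a) + block_cost(b))
  }
  best
}

random_mixed_df <- function(n, p = 2, q = 2, n_lev = 3) {
  data.frame(
    as.data.frame(matrix(round(stats::runif(n * p, 0, 10), 2), n, p,
                         dimnames = list(NULL, paste0("x", 1:p)))),
    as.data.frame(matrix(sample(letters[1:n_lev], n * q, replace = TRUE),
                         n, q, dimnames = list(NULL, paste0("c", 1:q))),
                  stringsAsFactors = FALSE),
    stringsAsFactors = FALSE)
}
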