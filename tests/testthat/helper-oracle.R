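# Independent brute-force estimators used as oracles. Everything here is
# written as plain per-child loops with no shared code with the package's
# estimators (beyond the public kernel/period conventions they both
# implement).

AG_BREAKS <- c(0, 1, 12, 24, 36, 48)
AG_NMONTHS <- c(1, 11, 12, 12, 12, 12)

oracle_group <- function(age) findInterval(age, AG_BREAKS)

# Enumerate the observed child-months of one child as a data.frame.
oracle_child_months <- function(birth_cmc, alive, death_age, interview_cmc) {
  dead_u5 <- !alive && !is.na(death_age) && death_age <= 59
  last <- if (dead_u5) {
    min(death_age, interview_cmc - birth_cmc - 1)
  } else {
    min(59, interview_cmc - birth_cmc - 1)
  }
  if (last < 0) {
    return(data.frame(cmc = integer(), age = integer(),
                      ends_alive = logical()))
  }
  age <- 0:last
  data.frame(cmc = birth_cmc + age, age = age,
             ends_alive = !(dead_u5 & age == death_age))
}

oracle_all_child_months <- function(ds) {
  rows <- list()
  for (i in seq_len(nrow(ds$children))) {
    ch <- ds$children[i]
    icmc <- ds$women$interview_cmc[ds$women$woman_id == ch$woman_id]
    rows[[i]] <- oracle_child_months(ch$birth_cmc, ch$alive_at_survey,
                                     ch$death_age_months, icmc)
  }
  do.call(rbind, c(rows, list(data.frame(cmc = integer(), age = integer(),
                                         ends_alive = logical()))))
}

# q5 from weighted per-group tallies, groups combined in m0..m48_59 order.
oracle_q5 <- function(tot, alive) {
  present <- which(tot > 0)
  if (!length(present)) return(NA_real_)
  p <- alive[present] / tot[present]
  1 - prod(p^AG_NMONTHS[present])
}

oracle_standard <- function(ds, length_years, anchor_cmc = NULL) {
  if (is.null(anchor_cmc)) anchor_cmc <- ds$interview_cmc_max
  cm <- oracle_all_child_months(ds)
  cm <- cm[cm$cmc <= anchor_cmc, , drop = FALSE]
  pl <- 12 * length_years
  out <- data.frame(time_years = numeric(), q5 = numeric(),
                    n_child_months = numeric())
  if (!nrow(cm)) return(out)
  k <- (anchor_cmc - cm$cmc) %/% pl
  for (kk in sort(unique(k))) {
    sub <- cm[k == kk, , drop = FALSE]
    tot <- alive <- numeric(6)
    for (j in seq_len(nrow(sub))) {
      g <- oracle_group(sub$age[j])
      tot[g] <- tot[g] + 1
      alive[g] <- alive[g] + sub$ends_alive[j]
    }
    out <- rbind(out, data.frame(
      time_years = 1900 + (anchor_cmc - pl * kk - pl / 2) / 12,
      q5 = oracle_q5(tot, alive), n_child_months = sum(tot)
    ))
  }
  out[order(out$time_years), , drop = FALSE]
}

oracle_moving_window <- function(ds, window_years, kernel, target_years) {
  cm <- oracle_all_child_months(ds)
  half <- window_years / 2
  out <- data.frame(time_years = numeric(), q5 = numeric(),
                    n_child_months = numeric())
  for (T in target_years) {
    tot <- alive <- numeric(6)
    for (j in seq_len(nrow(cm))) {
      u <- abs(1900 + (cm$cmc[j] - 0.5) / 12 - (T + 0.5))
      w <- if (kernel == "flat") as.numeric(u <= half) else max(0, 1 - u / half)
      if (w == 0) next
      g <- oracle_group(cm$age[j])
      tot[g] <- tot[g] + w
      alive[g] <- alive[g] + w * cm$ends_alive[j]
    }
    if (sum(tot) == 0) next
    out <- rbind(out, data.frame(time_years = T + 0.5,
                                 q5 = oracle_q5(tot, alive),
                                 n_child_months = sum(tot)))
  }
  out
}

# Random tiny survey (<= 20 children) for oracle cross-checks.
random_tiny_survey <- function(seed) {
  set.seed(seed)
  interview <- sample(900:1300, 1)
  n_women <- sample(2:8, 1)
  women <- data.frame(woman_id = paste0("w", seq_len(n_women)),
                      interview_cmc = interview)
  kids <- list()
  cid <- 0
  for (w in seq_len(n_women)) {
    for (k in seq_len(sample(0:2, 1))) {
      cid <- cid + 1
      birth <- interview - sample(0:80, 1)
      dead <- runif(1) < 0.35
      d <- if (dead) sample(0:70, 1) else NA_integer_
      kids[[cid]] <- data.frame(
        woman_id = paste0("w", w), child_id = paste0("c", cid),
        birth_cmc = birth, alive_at_survey = !dead, death_age_months = d
      )
    }
  }
  children <- if (length(kids)) do.call(rbind, kids) else
    data.frame(woman_id = character(), child_id = character(),
               birth_cmc = integer(), alive_at_survey = logical(),
               death_age_months = integer())
  bh_survey(paste0("tiny", seed), "TT", women, children)
}
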