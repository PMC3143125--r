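# Independent brute-force oracles. These deliberately share no code with
# the package: medians are computed by explicit sorting, regressions by
# closed-form normal equations, and ROC quantities by exhaustive pair or
# threshold enumeration.

# sort-based median, midpoint convention for even counts
oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# pairwise rank probability P(case more disease-like than control),
# half credit for ties
oracle_auc <- function(scores, labels, direction = "low") {
  cases <- scores[as.logical(labels)]
  ctrls <- scores[!as.logical(labels)]
  tot <- 0
  for (x in cases) for (y in ctrls) {
    more_diseased <- if (direction == "low") x < y else x > y
    tot <- tot + if (x == y) 0.5 else as.numeric(more_diseased)
  }
  tot / (length(cases) * length(ctrls))
}

# exhaustive threshold scan for the best TPR at FPR <= target
oracle_sens_at_fpr <- function(scores, labels, fpr_target,
                               direction = "low") {
  labels <- as.logical(labels)
  best <- 0
  for (t in c(-Inf, Inf, unique(scores))) {
    pos <- if (direction == "low") scores <= t else scores >= t
    fpr <- sum(pos & !labels) / sum(!labels)
    tpr <- sum(pos & labels) / sum(labels)
    if (fpr <= fpr_target + 1e-12 && tpr > best) best <- tpr
  }
  100 * best
}

# from-scratch refit of the whole normalization pipeline with one subject
# held out, returning the out-of-sample first-trimester blood-group
# adjusted MoM(s) of that subject
oracle_loo_score <- function(subjects, samples, sid,
                             order = c("bmi", "ethnicity", "smoking",
                                       "age", "parity"),
                             min_count_group = 5) {
  if (!"trimester" %in% names(samples))
    samples$trimester <- assign_trimester(samples$ga_week)
  rest_s <- subjects[subjects$subject_id != sid, ]
  rest_m <- samples[samples$subject_id != sid, ]
  dat <- merge(rest_m, rest_s, by = "subject_id")
  un <- dat[dat$outcome == "unaffected", ]

  weeks <- sort(unique(un$ga_week))
  med <- vapply(weeks, function(w)
    oracle_median(un$concentration_pg_ml[un$ga_week == w]), numeric(1))
  names(med) <- weeks
  lookup <- function(w) {
    if (as.character(w) %in% names(med)) return(med[as.character(w)])
    med[order(abs(weeks - w), weeks)][1]
  }

  y <- log(un$concentration_pg_ml / vapply(un$ga_week, lookup, numeric(1)))
  terms <- list()
  for (cv in order) {
    x <- un[[cv]]
    if (is.character(x)) {
      lv <- sort(unique(x))
      adj <- vapply(lv, function(l) mean(y[x == l]), numeric(1)) - mean(y)
      names(adj) <- lv
      terms[[cv]] <- list(kind = "cat", adj = adj)
      y <- y - adj[x]
    } else {
      x <- as.numeric(x)
      mx <- mean(x)
      b <- if (sum((x - mx)^2) == 0) 0 else
        sum((x - mx) * (y - mean(y))) / sum((x - mx)^2)
      terms[[cv]] <- list(kind = "num", b = b, mx = mx)
      y <- y - b * (x - mx)
    }
  }
  adj_mom <- exp(y)

  fac <- list()
  for (g in c("O", "A", "B", "AB")) for (tr in sort(unique(un$trimester))) {
    v <- adj_mom[un$blood_group == g & un$trimester == tr]
    fac[[paste(g, tr)]] <- if (length(v) >= min_count_group)
      oracle_median(v) else 1.0
  }

  subj <- subjects[subjects$subject_id == sid, ]
  own <- samples[samples$subject_id == sid & samples$trimester == 1, ]
  out <- numeric(nrow(own))
  for (k in seq_len(nrow(own))) {
    y0 <- log(own$concentration_pg_ml[k] / lookup(own$ga_week[k]))
    for (cv in order) {
      tm <- terms[[cv]]
      if (tm$kind == "num") {
        y0 <- y0 - tm$b * (as.numeric(subj[[cv]]) - tm$mx)
      } else {
        a <- tm$adj[as.character(subj[[cv]])]
        y0 <- y0 - if (is.na(a)) 0 else a
      }
    }
    out[k] <- exp(y0) / fac[[paste(subj$blood_group, 1)]]
  }
  stats::setNames(out, own$ga_week)
}

# small deterministic cohort builder for exact-identity tests: one week,
# fixed blood-group block sizes, hand-set concentrations
build_fixed_cohort <- function(conc, blood_group, ga_week = 8,
                               outcome = "unaffected") {
  n <- length(conc)
  subjects <- data.frame(
    subject_id = sprintf("F%03d", seq_len(n)),
    blood_group = rep_len(blood_group, n),
    rh = "+",
    outcome = rep_len(outcome, n),
    bmi = 24, age = 29, smoking = FALSE, parity = 1,
    ethnicity = "eth1",
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    subject_id = subjects$subject_id,
    ga_week = rep_len(ga_week, n),
    concentration_pg_ml = conc,
    stringsAsFactors = FALSE
  )
  list(subjects = subjects, samples = samples)
}
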