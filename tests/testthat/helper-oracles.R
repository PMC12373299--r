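# Independent brute-force oracles and random fixture builders. Every
# oracle here is written as naively as possible: plain double loops and
# direct definitions, sharing no code path with the implementation.

# --- random toy patients ----------------------------------------------------

random_toy_script <- function(seed) {
  set.seed(seed)
  n <- sample(1:12, 1)
  days <- sort(sample(0:1400, n))
  domains <- c("articular", "cutaneous", "hematological", "neurological",
               "renal", "vascular", "serosal", "systemic")
  depts <- c("hematology", "nephrology", "dermatology", "neurology",
             "angiology", "infectious_diseases", "orthopedics", "other")
  lapply(seq_len(n), function(i) {
    type <- sample(c("outpatient", "admission", "day_hospital"), 1,
                   prob = c(0.6, 0.25, 0.15))
    s <- list(day = days[i], type = type)
    if (type == "admission") {
      s$dept <- sample(depts, 1)
      s$icd9 <- sample(c("710.0", "695.4", "401.9", "486"),
                       sample(1:2, 1))
      if (runif(1) < 0.3) {
        s$infusion_drug <- sample(c("cyclophosphamide", "rituximab"), 1)
        s$infusion_is_first <- runif(1) < 0.5
      }
    }
    if (runif(1) < 0.4) s$involvements <- sample(domains, sample(1:2, 1))
    if (runif(1) < 0.35) s$manifestations <- sample(domains, 1)
    if (runif(1) < 0.3) s$therapy_change <- sample(c("step_up", "step_down"), 1)
    if (runif(1) < 0.5) {
      s$treatments <- sample(c("glucocorticoids", "antimalarials",
                               "immunosuppressants"), sample(1:2, 1))
    } else if (runif(1) < 0.3) {
      s$treatments <- NA
    }
    if (runif(1) < 0.5) {
      labs <- sample(c("albuminuria", "proteinuria", "creatinine"),
                     sample(1:2, 1))
      s$labs <- stats::setNames(sample(c("normal", "out_of_range"),
                                       length(labs), replace = TRUE), labs)
    }
    s
  })
}

random_toy_patient <- function(seed) {
  make_toy_patient(random_toy_script(seed),
                   patient_id = sprintf("T%04d", seed),
                   sex = if (seed %% 3 == 0) "male" else "female")
}

# --- labeling oracle --------------------------------------------------------

# Naive re-derivation of the composite event and the forward-window label:
# double loop over (contact, later contact) pairs.
oracle_labels <- function(contacts, window_days = 365) {
  contacts <- contacts[order(contacts$contact_date), ]
  n <- nrow(contacts)
  domains <- c("articular", "cutaneous", "hematological", "neurological",
               "renal", "vascular", "serosal", "systemic")
  inv_at <- function(k) {
    domains[vapply(domains, function(d)
      contacts[[paste0("involvement_", d)]][k] == 1, logical(1))]
  }
  event <- logical(n)
  for (k in seq_len(n)) {
    prior <- character(0)
    if (k > 1) for (j in 1:(k - 1)) prior <- union(prior, inv_at(j))
    nrv_man <- any(vapply(c("neurological", "renal", "vascular"), function(d)
      contacts[[paste0("manifestation_", d)]][k] == 1, logical(1)))
    new_inv <- length(setdiff(inv_at(k), prior)) > 0
    hosp <- FALSE
    if (contacts$contact_type[k] == "admission") {
      codes <- strsplit(contacts$icd9_codes[k], ";")[[1]]
      sle <- any(codes %in% c("710.0", "695.4"))
      dept <- contacts$department[k]
      dept_ok <- !is.na(dept) && dept %in% c("hematology", "nephrology",
                                             "dermatology", "neurology",
                                             "angiology")
      cont <- !is.na(contacts$infusion_drug[k]) && !contacts$infusion_is_first[k]
      hosp <- sle && dept_ok && !cont
    }
    event[k] <- nrv_man || new_inv || hosp
  }
  out <- integer(n)
  cens <- logical(n)
  for (k in seq_len(n)) {
    hit <- FALSE
    for (u in seq_len(n)) {
      gap <- as.numeric(contacts$contact_date[u] - contacts$contact_date[k])
      if (gap > 0 && gap <= window_days && event[u]) hit <- TRUE
    }
    out[k] <- as.integer(hit)
    cens[k] <- !hit &&
      as.numeric(contacts$contact_date[n] - contacts$contact_date[k]) < window_days
  }
  list(outcome = out, censored = cens, event = event)
}

# --- feature-window oracle --------------------------------------------------

# Naive per-contact aggregation of the last-window and history blocks for a
# representative set of engineered features.
oracle_windows <- function(contacts, window_days = 365) {
  contacts <- contacts[order(contacts$contact_date), ]
  n <- nrow(contacts)
  day <- as.numeric(contacts$contact_date - contacts$contact_date[1])
  domains <- c("articular", "cutaneous", "hematological", "neurological",
               "renal", "vascular", "serosal", "systemic")
  new_inv_flag <- integer(n)
  for (k in seq_len(n)) {
    prior <- character(0)
    if (k > 1) for (j in 1:(k - 1)) {
      prior <- union(prior, domains[vapply(domains, function(d)
        contacts[[paste0("involvement_", d)]][j] == 1, logical(1))])
    }
    now <- domains[vapply(domains, function(d)
      contacts[[paste0("involvement_", d)]][k] == 1, logical(1))]
    new_inv_flag[k] <- as.integer(length(setdiff(now, prior)) > 0)
  }
  res <- list()
  for (k in seq_len(n)) {
    last <- integer(0)
    past <- integer(0)
    for (j in seq_len(n)) {
      if (day[j] < day[k]) past <- c(past, j)
      if (day[j] < day[k] && day[j] > day[k] - window_days) last <- c(last, j)
    }
    res[[k]] <- data.frame(
      cur_delta_contacts = if (k == 1) -1 else day[k] - day[k - 1],
      cur_new_involvement = new_inv_flag[k],
      last_n_outpatient = sum(contacts$contact_type[last] == "outpatient"),
      last_n_admission = sum(contacts$contact_type[last] == "admission"),
      last_n_day_hospital = sum(contacts$contact_type[last] == "day_hospital"),
      last_any_admission = as.integer(any(contacts$contact_type[last] == "admission")),
      last_any_new_involvement = as.integer(any(new_inv_flag[last] == 1)),
      last_any_step_down = as.integer(any(contacts$therapy_change[last] == "step_down")),
      past_n_contacts = length(past),
      past_any_outpatient = as.integer(any(contacts$contact_type[past] == "outpatient")),
      past_any_step_down = as.integer(any(contacts$therapy_change[past] == "step_down")),
      past_n_step_down = sum(contacts$therapy_change[past] == "step_down"),
      past_inv_renal_ever = as.integer(any(contacts$involvement_renal[past] == 1))
    )
  }
  do.call(rbind, res)
}

# --- quantile oracle --------------------------------------------------------

# Linear-interpolation quantile written from the definition.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# --- AUC oracle -------------------------------------------------------------

# Pairwise win fraction over all (positive, negative) pairs, ties 1/2.
oracle_auc <- function(pp, y) {
  pos <- pp[y == 1]
  neg <- pp[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (if (a > b) 1 else if (a == b) 0.5 else 0)
  }
  total / (length(pos) * length(neg))
}

# --- Shapley oracle ---------------------------------------------------------

# Exact Shapley values for a single unified tree by subset enumeration over
# the features the tree uses, with the path-dependent (cover-weighted)
# conditional expectation.
oracle_tree_expect <- function(tree, x, S) {
  rec <- function(node) {
    f <- tree$feature[node + 1]
    if (f < 0) return(tree$value[node + 1])
    if ((f + 1) %in% S) {
      go_yes <- if (tree$strict_lt) x[f + 1] < tree$threshold[node + 1]
      else x[f + 1] <= tree$threshold[node + 1]
      rec(if (go_yes) tree$yes[node + 1] else tree$no[node + 1])
    } else {
      (tree$cover[tree$yes[node + 1] + 1] * rec(tree$yes[node + 1]) +
         tree$cover[tree$no[node + 1] + 1] * rec(tree$no[node + 1])) /
        tree$cover[node + 1]
    }
  }
  rec(0)
}

oracle_tree_shap <- function(tree, x, p) {
  used <- sort(unique(tree$feature[tree$feature >= 0])) + 1
  phi <- numeric(p)
  u <- length(used)
  # enumerate subsets of used \ {i}; combn() needs a guard against its
  # scalar-first-argument expansion
  safe_combn <- function(v, m) {
    if (m == 0) return(list(integer(0)))
    if (length(v) < m) return(list())
    if (length(v) == 1) return(list(v))
    utils::combn(v, m, simplify = FALSE)
  }
  for (i in used) {
    others <- setdiff(used, i)
    k <- length(others)
    idx_sets <- unlist(lapply(0:k, function(sz) safe_combn(others, sz)),
                       recursive = FALSE)
    for (S in idx_sets) {
      w <- factorial(length(S)) * factorial(u - length(S) - 1) / factorial(u)
      phi[i] <- phi[i] + w * (oracle_tree_expect(tree, x, c(S, i)) -
                                oracle_tree_expect(tree, x, S))
    }
  }
  phi
}
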