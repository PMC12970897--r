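# fixture builders and independent reference implementations used across tests

`%||%` <- function(x, y) if (is.null(x)) y else x

srs_roles_all <- function() c("PS", "SS", "concomitant", "interacting", "suspect")

write_lines_to <- function(lines, dir, file) {
  writeLines(lines, file.path(dir, file))
  invisible(file.path(dir, file))
}

# minimal FAERS-dialect quarter: 3 cases, one with two versions of the same
# caseid; montelukast PS + EGPA on case 1
write_faers_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_lines_to(c(
    "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$wt$occr_country$occp_cod",
    "1001$C1$20230101$20221201$45$YR$F$70$US$MD",
    "1002$C1$20240101$20221201$45$YR$F$70$US$MD",
    "2001$C2$20230315$$61$YR$M$82$GB$PH",
    "3001$C3$20230601$20230520$8$YR$F$28$US$CN"
  ), dir, "DEMO24Q1.txt")
  write_lines_to(c(
    "primaryid$caseid$drug_seq$role_cod$drugname",
    "1001$C1$1$PS$SINGULAIR",
    "1002$C1$1$PS$SINGULAIR",
    "1002$C1$2$C$PREDNISONE",
    "2001$C2$1$PS$ASPIRIN",
    "3001$C3$1$PS$Montelukast Sodium"
  ), dir, "DRUG24Q1.txt")
  write_lines_to(c(
    "primaryid$caseid$pt",
    "1001$C1$Eosinophilic granulomatosis with polyangiitis",
    "1002$C1$Eosinophilic granulomatosis with polyangiitis",
    "2001$C2$Headache",
    "3001$C3$Rash"
  ), dir, "REAC24Q1.txt")
  write_lines_to(c(
    "primaryid$caseid$dsg_drug_seq$start_dt",
    "1002$C1$1$20220115",
    "3001$C3$1$202303"
  ), dir, "THER24Q1.txt")
  write_lines_to(c(
    "primaryid$caseid$indi_drug_seq$indi_pt",
    "1002$C1$1$Asthma",
    "3001$C3$1$Rhinitis"
  ), dir, "INDI24Q1.txt")
  write_lines_to(c(
    "primaryid$caseid$outc_cod",
    "1002$C1$HO",
    "1002$C1$OT"
  ), dir, "OUTC24Q1.txt")
  dir
}

write_jader_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_lines_to(c(
    "caseid,sex,age,weight,reporter",
    "J1,female,50,55,physician",
    "J2,male,70,68,pharmacist"
  ), dir, "demo.csv")
  write_lines_to(c(
    "caseid,drugname,role,start_date,indication",
    "J1,ONON,suspect,20200110,Asthma",
    "J1,ONON,suspect,20200110,Asthma",
    "J2,KIPRES,suspect,20210301,Asthma"
  ), dir, "drug.csv")
  write_lines_to(c(
    "caseid,pt,onset_date",
    "J1,Eosinophilic granulomatosis with polyangiitis,20200601",
    "J2,Headache,20210401"
  ), dir, "reac.csv")
  dir
}

write_cvar_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()), orphan = FALSE) {
  write_lines_to(c(
    "Report_ID,age,sex,weight,country",
    "V1,33,Female,60,CA",
    "V2,58,Male,90,CA"
  ), dir, "reports.csv")
  drug_rows <- c(
    "Report_ID,drugname,role,start_date",
    "V1,montelukast,Suspect,20190501",
    "V2,aspirin,Concomitant,20190601"
  )
  if (orphan) drug_rows <- c(drug_rows, "V9,montelukast,Suspect,20190801")
  write_lines_to(drug_rows, dir, "report_drug.csv")
  write_lines_to(c(
    "Report_ID,pt,onset_date",
    "V1,Churg-Strauss syndrome,20190915",
    "V2,Nausea,20190610"
  ), dir, "reactions.csv")
  dir
}

# hand-built dataset with exact counts: n_both drug+event, n_drug_only,
# n_event_only, n_neither; index drug carries role PS
toy_dataset <- function(n_both = 1, n_drug = 1, n_event = 1, n_neither = 1,
                        drug = "drugx", pt = "Event of interest",
                        ages = NULL, sexes = NULL) {
  n <- n_both + n_drug + n_event + n_neither
  ids <- sprintf("R%04d", seq_len(n))
  cases <- tibble::tibble(report_id = ids, case_id = ids, version_key = ids,
                          age = ages %||% rep(NA_real_, n),
                          sex = sexes %||% rep("unknown", n))
  exposed <- ids[seq_len(n_both + n_drug)]
  with_event <- ids[c(seq_len(n_both),
                      n_both + n_drug + seq_len(n_event))]
  drugs <- tibble::tibble(report_id = exposed, verbatim_name = drug,
                          ingredient = drug, role = "PS")
  events <- tibble::tibble(report_id = with_event, pt = pt)
  srs_dataset(cases, drugs, events, dialect = "synthetic")
}

# ---- independent MCODE reference (adjacency-matrix transcription) ---------

ref_k_core_members <- function(A, k) {
  alive <- rep(TRUE, nrow(A))
  repeat {
    d <- vapply(seq_len(nrow(A)), function(i) sum(A[i, alive]), 0)
    drop <- alive & d < k
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  which(alive)
}

ref_core_numbers <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    kmax <- 0
    for (k in seq_len(n)) {
      if (v %in% ref_k_core_members(A, k)) kmax <- k else break
    }
    kmax
  }, 0)
}

ref_density <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  sum(A) / (n * (n - 1))
}

ref_mcode_weights <- function(A, degree_cutoff) {
  n <- nrow(A)
  w <- numeric(n)
  for (v in seq_len(n)) {
    if (sum(A[v, ]) < degree_cutoff) next
    nb <- sort(unique(c(v, which(A[v, ] > 0))))
    B <- A[nb, nb, drop = FALSE]
    cn <- ref_core_numbers(B)
    kmax <- max(cn)
    if (kmax == 0) next
    mem <- which(cn == kmax)
    w[v] <- kmax * ref_density(B[mem, mem, drop = FALSE])
  }
  w
}

ref_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0) next
    cur <- cur + 1L
    stack <- v
    while (length(stack)) {
      x <- stack[[1]]; stack <- stack[-1]
      if (comp[x] > 0) next
      comp[x] <- cur
      stack <- c(stack, which(A[x, ] > 0 & comp == 0))
    }
  }
  comp
}

ref_mcode <- function(A, names_v, degree_cutoff = 2, node_score_cutoff = 0.2,
                      k_core = 2, haircut = TRUE, max_depth = 100) {
  n <- nrow(A)
  w <- ref_mcode_weights(A, degree_cutoff)
  ord <- order(-w, names_v, method = "radix")
  seen <- rep(FALSE, n)
  clusters <- list()
  for (seed in ord) {
    if (seen[seed] || w[seed] <= 0) next
    thresh <- w[seed] * (1 - node_score_cutoff)
    members <- seed; seen[seed] <- TRUE
    frontier <- seed; depth <- 0
    while (length(frontier) && depth < max_depth) {
      nxt <- integer(0)
      for (v in frontier) for (u in which(A[v, ] > 0)) {
        if (!seen[u] && w[u] >= thresh) {
          seen[u] <- TRUE; members <- c(members, u); nxt <- c(nxt, u)
        }
      }
      frontier <- nxt; depth <- depth + 1
    }
    B <- A[members, members, drop = FALSE]
    cn <- ref_core_numbers(B)
    if (max(cn) < k_core) next
    if (haircut) {
      keep <- members[cn >= 2]
      if (!seed %in% keep) keep <- unique(c(seed, keep))
      members <- keep
    }
    B <- A[members, members, drop = FALSE]
    comp <- ref_components(B)
    members <- members[comp == comp[match(seed, members)]]
    if (length(members) < 2) next
    B <- A[members, members, drop = FALSE]
    dens <- ref_density(B)
    clusters[[length(clusters) + 1]] <- list(
      members = sort(names_v[members]), seed = names_v[seed],
      score = dens * length(members), size = length(members))
  }
  if (length(clusters)) {
    key <- order(-vapply(clusters, `[[`, 0, "score"),
                 -vapply(clusters, `[[`, 0L, "size"),
                 vapply(clusters, `[[`, "", "seed"), method = "radix")
    clusters <- clusters[key]
  }
  clusters
}

random_graph <- function(n, p) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) A[i, j] <- A[j, i] <- 1L
  }
  dimnames(A) <- list(letters[seq_len(n)], letters[seq_len(n)])
  A
}

graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# ---- EBGM numerical-integration oracle ------------------------------------

oracle_posterior <- function(a, E, prior) {
  dens <- function(l) {
    pr <- prior$w * stats::dgamma(l, prior$alpha1, rate = prior$beta1) +
      (1 - prior$w) * stats::dgamma(l, prior$alpha2, rate = prior$beta2)
    pr * stats::dpois(a, l * E)
  }
  # split the range around the posterior bulk so adaptive quadrature
  # never overlooks a narrow peak far from the interval midpoint
  peak <- (a + 1) / E
  knots <- sort(unique(c(0, peak / 100, peak / 10, peak, peak * 10, peak * 100)))
  int_piecewise <- function(f, upper = Inf) {
    ks <- c(knots[knots < upper], upper)
    tot <- 0
    for (i in seq_len(length(ks) - 1)) {
      tot <- tot + stats::integrate(f, ks[i], ks[i + 1],
                                    rel.tol = 1e-12, abs.tol = 0)$value
    }
    tot
  }
  Z <- int_piecewise(dens)
  mean_log <- int_piecewise(function(l) log(l) * dens(l)) / Z
  cdf <- function(x) int_piecewise(dens, upper = x) / Z
  q05 <- stats::uniroot(function(x) cdf(x) - 0.05, lower = 1e-12,
                        upper = peak * 100, tol = 1e-12)$root
  list(ebgm = exp(mean_log), eb05 = q05)
}
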