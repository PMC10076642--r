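# Fixtures are built in code at test time; nothing binary is shipped.

# Write the tiny 3-report FAERS-style fixture and return the five paths.
write_tiny_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  w <- function(file, lines) {
    path <- file.path(dir, file)
    writeLines(lines, path)
    path
  }
  c(
    demo = w("DEMO.txt", c(
      "primaryid$caseid$caseversion$quarter$age$sex$country$onset_months",
      "A-1$A$1$2016Q2$45$female$US$2",
      "B-1$B$1$2017Q1$$male$FR$",
      "C-1$C$1$2020Q3$61$unknown$$"
    )),
    drug = w("DRUG.txt", c(
      "primaryid$drug_seq$role_cod$drugname",
      "A-1$1$PS$COSENTYX 150MG",
      "A-1$2$C$ASPIRIN",
      "B-1$1$PS$TALTZ",
      "C-1$1$SS$secukinumab",
      "C-1$2$PS$METHOTREXATE"
    )),
    reac = w("REAC.txt", c(
      "primaryid$pt",
      "A-1$Crohn's disease",
      "A-1$Colitis",
      "B-1$Colitis ulcerative",
      "C-1$Drug ineffective"
    )),
    outc = w("OUTC.txt", c(
      "primaryid$outc_cod",
      "A-1$HO",
      "B-1$OT",
      "B-1$HO"
    )),
    indi = w("INDI.txt", c(
      "primaryid$indi_drug_seq$indi_pt",
      "A-1$1$Psoriasis"
    ))
  )
}

read_fixture <- function(paths) {
  suppressMessages(read_quarter_files(paths["demo"], paths["drug"],
                                      paths["reac"], paths["outc"],
                                      paths["indi"]))
}

# Minimal in-memory collection: one row per report, drugs/reactions given
# as lists of (role, name) and PT character vectors.
make_reports <- function(drugs, reactions, caseid = NULL, caseversion = NULL,
                         quarter = NULL) {
  n <- length(drugs)
  primaryid <- sprintf("R%03d", seq_len(n))
  if (is.null(caseid)) caseid <- primaryid
  if (is.null(caseversion)) caseversion <- rep(1L, n)
  if (is.null(quarter)) quarter <- rep("2018Q1", n)
  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     caseversion = caseversion, quarter = quarter,
                     age = NA_real_, sex = "unknown",
                     country = NA_character_, onset_months = NA_real_)
  drug <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- drugs[[i]]
    data.frame(primaryid = primaryid[i], drug_seq = seq_along(d$role),
               role_cod = d$role, drugname = d$name,
               indi_pt = NA_character_)
  }))
  reac <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(primaryid = primaryid[i], pt = reactions[[i]])
  }))
  empty_outc <- data.frame(primaryid = character(), outc_cod = character())
  empty_indi <- data.frame(primaryid = character(),
                           indi_drug_seq = integer(),
                           indi_pt = character())
  faers_reports(demo, drug, reac, empty_outc, empty_indi)
}

# Random small collection for brute-force oracle comparisons.
random_reports <- function(n, seed) {
  set.seed(seed)
  drug_pool <- c("COSENTYX 150MG", "SECUKINUMAB", "TALTZ", "ASPIRIN",
                 "METHOTREXATE", "IBUPROFEN")
  pt_pool <- c("Crohn's disease", "Colitis", "Colitis ulcerative",
               "Headache", "Nausea", "Drug ineffective")
  drugs <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    list(role = sample(c("PS", "SS", "C", "I"), k, replace = TRUE),
         name = sample(drug_pool, k, replace = TRUE))
  })
  reactions <- lapply(seq_len(n), function(i) {
    # duplicates on purpose: distinct-PT counting must collapse them
    sample(pt_pool, sample(1:4, 1), replace = TRUE)
  })
  make_reports(drugs, reactions)
}

# Brute-force event-level 2x2 oracle: per report, per *distinct* PT,
# written independently of build_contingency.
brute_contingency <- function(reports, active, dictionary, pts) {
  pts <- tolower(trimws(pts))
  a <- b <- cc <- d <- 0L
  for (id in reports$demo$primaryid) {
    dr <- reports$drugs[reports$drugs$primaryid == id &
                          reports$drugs$role_cod == "PS", ]
    exposed <- FALSE
    for (nm in dr$drugname) {
      hit <- match_drug(nm, dictionary)
      if (!is.na(hit) && hit == active) exposed <- TRUE
    }
    rpts <- unique(tolower(trimws(
      reports$reactions$pt[reports$reactions$primaryid == id])))
    for (p in rpts) {
      if (exposed && p %in% pts) a <- a + 1L
      else if (exposed) b <- b + 1L
      else if (p %in% pts) cc <- cc + 1L
      else d <- d + 1L
    }
  }
  c(a = a, b = b, c = cc, d = d)
}
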