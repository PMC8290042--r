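#!/usr/bin/env Rscript
# Regenerates the committed golden outputs for the CLI reproducibility test.
# Run from the repository root with the package installed:
#   Rscript scripts/make_golden.R

cli <- system.file("cli", "placeconn.R", package = "placeconn")
stopifnot(nzchar(cli))
rscript <- file.path(R.home("bin"), "Rscript")
golden <- file.path("tests", "testthat", "golden")
dir.create(golden, showWarnings = FALSE, recursive = TRUE)

work <- tempfile("golden_work_")
dir.create(work)

run <- function(...) {
  status <- system2(rscript, c(cli, ...), stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
}

run("simulate", "--grid", "6x6", "--states", "4", "--users", "400",
    "--beta", "1.7", "--gamma", "3", "--seed", "42", "--out-dir", work)
run("compute", "--events", file.path(work, "events.csv"),
    "--layer", file.path(work, "world.geojson"),
    "--start", "2019-01-01", "--end", "2020-01-01",
    "--min-users", "5", "--person-days", "home_based", "--out-dir", work)
run("decay", "--pci", file.path(work, "pci.csv"),
    "--layer", file.path(work, "world.geojson"),
    "--origin", "C01", "--out", file.path(work, "decay.csv"))
run("boundary", "--pci", file.path(work, "pci.csv"),
    "--layer", file.path(work, "world.geojson"),
    "--parents", file.path(work, "parents.csv"),
    "--out", file.path(work, "boundary.csv"))
run("regionalize", "--pci", file.path(work, "pci.csv"),
    "--summary", file.path(work, "place_summary.csv"),
    "--k", "4,9", "--min-users", "5",
    "--out", file.path(work, "regions.csv"))

for (f in c("pci.csv", "shared_users.csv", "place_summary.csv",
            "person_days.csv", "decay.csv", "boundary.csv", "regions.csv")) {
  file.copy(file.path(work, f), file.path(golden, f), overwrite = TRUE)
  cat("golden:", f, file.size(file.path(golden, f)), "bytes\n")
}
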