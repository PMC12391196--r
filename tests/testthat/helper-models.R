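# Small models built in code for the solver and calibration tests.

# the standard synthetic knee without attachment jitter (deterministic)
clean_knee <- function(seed = 3) {
  generate_knee(synthetic_knee_spec(seed = seed, attachment_jitter_sd = 0))
}

# a knee whose ligaments are far too slack to ever engage, so only contact
# and applied loads act
slack_knee <- function() {
  knee <- clean_knee()
  x <- get_parameters(knee)
  x[grepl("^X(1[0-4]|[1-9])$", names(x))] <- 1.5
  set_parameters(knee, x)
}

# a mirror-symmetric two-bundle knee: one lateral strap and its exact
# medial mirror (bundle names are labels only)
symmetric_knee <- function(r = 1.0, k = 100) {
  lat <- ligament_bundle("LCL", origins = c(-25, 0, 2),
                         insertions = c(-25, 0, -40), r = r, k = k)
  med <- ligament_bundle("sMCL_M", origins = c(25, 0, 2),
                         insertions = c(25, 0, -40), r = r, k = k)
  acl <- ligament_bundle("ACL_AM", origins = c(0, -5, -2),
                         insertions = c(0, 10, -22.2), r = 0.98, k = 80)
  pcl <- ligament_bundle("PCL_AL", origins = c(0, 5, -2),
                         insertions = c(0, -20, -26), r = 1.0, k = 70)
  contacts <- lapply(c(medial = 1, lateral = -1), function(sgn) {
    contact_element(if (sgn > 0) "medial" else "lateral",
                    condyle_center = c(sgn * 23, 0, 0), condyle_radius = 22,
                    plateau_point = c(sgn * 23, 0, -22.2),
                    dish_radius = 65)
  })
  knee_model(list(lat, med, acl, pcl), contacts)
}

# a knee whose contacts can never engage and with a single slack fiber:
# its total potential is identically zero in a neighborhood of neutral
inert_knee <- function() {
  b <- ligament_bundle("LCL", origins = c(-25, 0, 0),
                       insertions = c(-25, 0, -40), r = 1.5, k = 100)
  contacts <- lapply(c(medial = 1, lateral = -1), function(sgn) {
    contact_element(if (sgn > 0) "medial" else "lateral",
                    condyle_center = c(sgn * 23, 0, 0), condyle_radius = 10,
                    plateau_point = c(sgn * 23, 0, -500))
  })
  knee_model(list(b), contacts, settle_compression = 0)
}

random_coords <- function(n = 1) {
  lapply(seq_len(n), function(i) {
    gs_coords(stats::runif(1, 0, 120), stats::runif(1, -15, 15),
              stats::runif(1, -40, 40), stats::runif(1, -30, 30),
              stats::runif(1, -30, 30), stats::runif(1, -30, 30))
  })
}
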