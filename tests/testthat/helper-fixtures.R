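# shared fixtures: one bone model set and one random-rigid-transform helper

fixture_models <- make_bone_models(side = "right", seed = 1)
fixture_frames <- build_frames(fixture_models)

random_rigid <- function() {
  list(R = random_rotation(), t = stats::runif(3, -50, 50))
}

# a small subject record with round numbers, handy for trial tests
fixture_subject <- function(stance_ms = 319,
                            subtalar = c(df_pf = 6.1, ev_iv = 5.3, er_ir = 5.5),
                            talocrural = c(df_pf = 13.7, ev_iv = 2.9,
                                           er_ir = 3.5)) {
  tibble::tibble(
    subject_id = "T01", group = "control", side = "right",
    stance_ms = stance_ms, calcaneal_pitch = 20.8,
    navicular_height_change = 0.7,
    subtalar_df_pf = subtalar[["df_pf"]],
    subtalar_ev_iv = subtalar[["ev_iv"]],
    subtalar_er_ir = subtalar[["er_ir"]],
    talocrural_df_pf = talocrural[["df_pf"]],
    talocrural_ev_iv = talocrural[["ev_iv"]],
    talocrural_er_ir = talocrural[["er_ir"]]
  )
}

# ground-truth pose with the mesh centroid placed mid-field
centered_pose <- function(mesh, R = diag(3), depth = 150) {
  ctr <- colMeans(mesh$vertices)
  rigid_pose(R, c(0, 0, depth) - as.numeric(R %*% ctr))
}

render_pose <- function(mesh, pose, projection) {
  poly <- project_silhouette(mesh, pose, projection)
  rearfootkin:::rasterize_convex(poly, projection$image_size[1],
                                 projection$image_size[2]) * 1
}
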