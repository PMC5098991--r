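# Builds the replica trajectory program: a donor fish is simulated in the
# left lateral compartment, its trajectory downsampled to 2.5 s waypoints,
# and the commanded motion reconstructed with the 2 Hz / 10 deg
# peak-to-peak body-oscillation heading. Writes the waypoint list, the
# program trajectory, and the program's kinematic fingerprint.
source("analysis/00_config.R")

cfg <- study_config()
program <- make_study_program(cfg)

cat(sprintf("program: %d waypoints every %g s\n",
            nrow(program$waypoints), program$interval_s))

kin <- kinematics(program$trajectory)
cat(sprintf("replica mean speed: %.2f cm/s (live-donor target 1.69)\n",
            mean(kin$speed)))
cat(sprintf("mean depth below surface: %.2f cm\n",
            mean(program$trajectory$z_cm)))
t10 <- seq(0, 10 - 1 / 30, by = 1 / 30)
cat(sprintf("heading: mean %g deg, span %.2f deg\n",
            mean(heading_signal(t10, 1)),
            max(heading_signal(t10, 1)) - min(heading_signal(t10, 1))))

write.csv(program$waypoints, file.path(results_dir, "replica_waypoints.csv"),
          row.names = FALSE)
write.csv(as.data.frame(program$trajectory),
          file.path(results_dir, "replica_program.csv"), row.names = FALSE)

# speed distribution of the program (0.72 cm/s bins, as the protocol plots)
dm <- density_maps(program$trajectory, speeds = kin$speed,
                   geometry = cfg$geometry)
write.csv(dm$speed, file.path(results_dir, "replica_speed_distribution.csv"),
          row.names = FALSE)
cat("written: replica_waypoints.csv, replica_program.csv, replica_speed_distribution.csv\n")
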