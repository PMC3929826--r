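- id: 0
  label: Base case (current state)
  deltas: []
- id: 1
  label: Novice residents 2 -> 3
  deltas:
    stations.novice_resident.schedule.n_servers: 3
- id: 2
  label: Experienced residents 1 -> 2
  deltas:
    stations.experienced_resident.schedule.n_servers: 2
- id: 3
  label: Residents attend 10:00 -> 09:00, 200 -> 260 min
  deltas:
    stations.novice_resident.schedule.start: 540.0
    stations.novice_resident.schedule.duration: 260.0
    stations.experienced_resident.schedule.start: 540.0
    stations.experienced_resident.schedule.duration: 260.0
- id: 4
  label: Senior staff attends 10:45 -> 10:00, 100 -> 160 min
  deltas:
    stations.senior_staff.schedule.start: 600.0
    stations.senior_staff.schedule.duration: 160.0
- id: 5
  label: Admission start 07:30 -> 08:00
  deltas:
    admission_start: 480.0
- id: 6
  label: Mix of scenarios 1 and 2
  deltas:
    stations.novice_resident.schedule.n_servers: 3
    stations.experienced_resident.schedule.n_servers: 2
- id: 7
  label: Mix of scenarios 3 and 4
  deltas:
    stations.novice_resident.schedule.start: 540.0
    stations.novice_resident.schedule.duration: 260.0
    stations.experienced_resident.schedule.start: 540.0
    stations.experienced_resident.schedule.duration: 260.0
    stations.senior_staff.schedule.start: 600.0
    stations.senior_staff.schedule.duration: 160.0
- id: 8
  label: Mix of scenarios 1, 2 and 5
  deltas:
    stations.novice_resident.schedule.n_servers: 3
    stations.experienced_resident.schedule.n_servers: 2
    admission_start: 480.0
- id: 9
  label: Mix of scenarios 3, 4 and 5
  deltas:
    stations.novice_resident.schedule.start: 540.0
    stations.novice_resident.schedule.duration: 260.0
    stations.experienced_resident.schedule.start: 540.0
    stations.experienced_resident.schedule.duration: 260.0
    stations.senior_staff.schedule.start: 600.0
    stations.senior_staff.schedule.duration: 160.0
    admission_start: 480.0
- id: 10
  label: Mix of scenarios 1, 2, 3 and 4
  deltas:
    stations.novice_resident.schedule.n_servers: 3
    stations.experienced_resident.schedule.n_servers: 2
    stations.novice_resident.schedule.start: 540.0
    stations.novice_resident.schedule.duration: 260.0
    stations.experienced_resident.schedule.start: 540.0
    stations.experienced_resident.schedule.duration: 260.0
    stations.senior_staff.schedule.start: 600.0
    stations.senior_staff.schedule.duration: 160.0
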