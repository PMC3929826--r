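stations:
  registration:
    schedule:
      start: 450.0
      duration: 600.0
      n_servers: 1
    service:
      family: lognormal
      mean: 1.13
      sd: 0.44
      lower: 0.0
    discipline: fifo
  cash:
    schedule:
      start: 450.0
      duration: 600.0
      n_servers: 1
    service:
      family: lognormal
      mean: 0.2
      sd: 0.3
      lower: 0.0
    discipline: fifo
  novice_resident:
    schedule:
      start: 540.0
      duration: 260.0
      n_servers: 3
    service:
      family: lognormal
      mean: 3.46
      sd: 2.06
      lower: 0.0
    discipline: fifo
  experienced_resident:
    schedule:
      start: 540.0
      duration: 260.0
      n_servers: 2
    service:
      family: lognormal
      mean: 4.91
      sd: 0.93
      lower: 0.0
    discipline: fifo
  senior_staff:
    schedule:
      start: 600.0
      duration: 160.0
      n_servers: 1
    service:
      family: lognormal
      mean: 4.2
      sd: 0.93
      lower: 0.0
    discipline: fifo
  paraclinic:
    schedule:
      start: 450.0
      duration: 600.0
      n_servers: 1
    service:
      family: lognormal
      mean: 12.0
      sd: 8.0
      lower: 0.0
    discipline: fifo
classes:
  new:
    mix_probability: 0.4
    first_physician: experienced_resident
    p_consult_senior: 0.25
    p_paraclinic: 0.3
  followup_outpatient:
    mix_probability: 0.3
    first_physician: experienced_resident
    p_consult_senior: 0.25
    p_paraclinic: 0.3
  followup_prev_inpatient:
    mix_probability: 0.3
    first_physician: novice_resident
    p_consult_senior: 0.25
    p_paraclinic: 0.3
interarrival:
  family: clipped_normal
  mean: 4.2
  sd: 5.8
  lower: 0.0
admission_start: 450.0
admission_duration: 240.0
weights:
  novice_resident: 2.0
  experienced_resident: 2.0
  senior_staff: 1.0
n_reps: 1000
overtime: yes
paraclinic_return: no
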