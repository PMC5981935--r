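# Default model parameters: task timings (minutes), note-use assumption,
# category mix of submissions, and staff unit costs (GBP/hour) with the
# annual per-patient service charge (GBP).
timings:
  book_appointment: 3
  receive_econsult: 3
  close_off_with_contact: 3
  close_off_no_contact: 1.5
  face_to_face_appointment: 10
  telephone_consultation: 5
  process_minimal_notes: 2.5
  process_detailed_notes: 5
  sick_note: 4
  prescription_increment: 1
  other_followup_increment: 0.5
  change_of_details: 0.5
notes:
  detailed_fraction: 0.5
mix:
  admin_other_details: 0.12
  admin_fit_note: 0.15
  gp_no_action: 0.10
  gp_prescription: 0.20
  other_appointment: 0.13
  gp_phone_back: 0.15
  gp_appointment: 0.15
costs:
  gp_cost_per_hour: 95.08
  admin_cost_per_hour: 17.82
  conventional_booking_minutes: 3
  conventional_gp_minutes: 10
  annual_charge_per_patient: 0.63
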