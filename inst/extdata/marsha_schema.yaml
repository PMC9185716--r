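items:
- item_id: m_yelled
  text: They yelled, screamed or swore at me
  subscale: intimidation
  category: emotional
  screener: yes
  screener_excluded: no
  target_prevalence: 0.28
- item_id: m_photo_pressure
  text: They asked or pressured me for a nude or almost nude photo or video of me,
    when I did not want to give them one
  subscale: sexual
  category: technology
  screener: yes
  screener_excluded: no
  target_prevalence: 0.28
- item_id: m_trapped
  text: They made me feel like I could not break up with them or get out of the relationship
  subscale: social_control
  category: control
  screener: yes
  screener_excluded: no
  target_prevalence: 0.25
- item_id: m_stopped_talking
  text: They stopped talking to me and I felt punished, hurt, or scared
  subscale: social_control
  category: control
  screener: no
  screener_excluded: yes
  target_prevalence: 0.38
- item_id: m_phys01
  text: Placeholder physical victimization item 1
  subscale: physical
  category: physical
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_phys02
  text: Placeholder physical victimization item 2
  subscale: physical
  category: physical
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_phys03
  text: Placeholder physical victimization item 3
  subscale: physical
  category: physical
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_phys04
  text: Placeholder physical victimization item 4
  subscale: physical
  category: physical
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_phys05
  text: Placeholder physical victimization item 5
  subscale: physical
  category: physical
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_phys06
  text: Placeholder physical victimization item 6
  subscale: physical
  category: physical
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_sex01
  text: Placeholder sexual victimization item 1
  subscale: sexual
  category: sexual
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_sex02
  text: Placeholder sexual victimization item 2
  subscale: sexual
  category: sexual
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_sex03
  text: Placeholder sexual victimization item 3
  subscale: sexual
  category: sexual
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_sex04
  text: Placeholder sexual victimization item 4
  subscale: sexual
  category: sexual
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_sex05
  text: Placeholder sexual victimization item 5
  subscale: sexual
  category: sexual
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_emo01
  text: Placeholder emotional victimization item 1
  subscale: intimidation
  category: emotional
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_emo02
  text: Placeholder emotional victimization item 2
  subscale: intimidation
  category: emotional
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_emo03
  text: Placeholder emotional victimization item 3
  subscale: intimidation
  category: emotional
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_emo04
  text: Placeholder emotional victimization item 4
  subscale: intimidation
  category: emotional
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_emo05
  text: Placeholder emotional victimization item 5
  subscale: intimidation
  category: emotional
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_tech01
  text: Placeholder technology victimization item 1
  subscale: privacy_control
  category: technology
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_tech02
  text: Placeholder technology victimization item 2
  subscale: privacy_control
  category: technology
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_tech03
  text: Placeholder technology victimization item 3
  subscale: privacy_control
  category: technology
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_tech04
  text: Placeholder technology victimization item 4
  subscale: privacy_control
  category: technology
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_tech05
  text: Placeholder technology victimization item 5
  subscale: privacy_control
  category: technology
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_tech06
  text: Placeholder technology victimization item 6
  subscale: privacy_control
  category: technology
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_tech07
  text: Placeholder technology victimization item 7
  subscale: privacy_control
  category: technology
  screener: no
  screener_excluded: no
  target_prevalence: ~
- item_id: m_ctrl01
  text: Placeholder control victimization item 1
  subscale: social_control
  category: control
  screener: no
  screener_excluded: no
  target_prevalence: 0.15
- item_id: m_ctrl02
  text: Placeholder control victimization item 2
  subscale: social_control
  category: control
  screener: no
  screener_excluded: no
  target_prevalence: 0.15
- item_id: m_ctrl03
  text: Placeholder control victimization item 3
  subscale: social_control
  category: control
  screener: no
  screener_excluded: no
  target_prevalence: 0.15
- item_id: m_ctrl04
  text: Placeholder control victimization item 4
  subscale: social_control
  category: control
  screener: no
  screener_excluded: no
  target_prevalence: 0.15
- item_id: m_ctrl05
  text: Placeholder control victimization item 5
  subscale: social_control
  category: control
  screener: no
  screener_excluded: no
  target_prevalence: 0.15
- item_id: m_ctrl06
  text: Placeholder control victimization item 6
  subscale: social_control
  category: control
  screener: no
  screener_excluded: no
  target_prevalence: 0.15
- item_id: m_ctrl07
  text: Placeholder control victimization item 7
  subscale: social_control
  category: control
  screener: no
  screener_excluded: no
  target_prevalence: 0.15
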