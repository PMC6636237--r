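@prefix epo: <http://purl.example.org/epo#> .
@prefix skos: <http://www.w3.org/2004/02/skos/core#> .

epo:adnexal_blob_sign epo:definition "Inhomogeneous adnexal mass moving separately from the ovary." .
epo:adnexal_blob_sign epo:kind "sign" .
epo:adnexal_blob_sign epo:located_in epo:fallopian_tube .
epo:adnexal_blob_sign epo:requires_view epo:left_adnexal_view .
epo:adnexal_blob_sign epo:requires_view epo:right_adnexal_view .
epo:adnexal_blob_sign epo:suggests epo:tubal_ectopic_pregnancy .
epo:adnexal_blob_sign skos:prefLabel "adnexal blob sign" .
epo:adnexal_mass_separate_from_ovary epo:definition "Extra-ovarian adnexal mass." .
epo:adnexal_mass_separate_from_ovary epo:kind "sign" .
epo:adnexal_mass_separate_from_ovary epo:requires_view epo:left_adnexal_view .
epo:adnexal_mass_separate_from_ovary epo:requires_view epo:right_adnexal_view .
epo:adnexal_mass_separate_from_ovary epo:suggests epo:tubal_ectopic_pregnancy .
epo:adnexal_mass_separate_from_ovary skos:prefLabel "adnexal mass separate from the ovary" .
epo:b_mode epo:kind "ultrasound_mode" .
epo:b_mode skos:prefLabel "B mode" .
epo:bagel_sign epo:definition "Hyperechoic ring around an extrauterine gestational sac." .
epo:bagel_sign epo:kind "sign" .
epo:bagel_sign epo:requires_view epo:left_adnexal_view .
epo:bagel_sign epo:requires_view epo:right_adnexal_view .
epo:bagel_sign epo:suggests epo:tubal_ectopic_pregnancy .
epo:bagel_sign skos:prefLabel "bagel sign" .
epo:double_decidual_sac_sign epo:definition "Two concentric echogenic rings around the sac." .
epo:double_decidual_sac_sign epo:kind "sign" .
epo:double_decidual_sac_sign epo:requires_view epo:endometrium_magnified_view .
epo:double_decidual_sac_sign epo:requires_view epo:uterus_sagittal_view .
epo:double_decidual_sac_sign epo:suggests epo:intrauterine_pregnancy .
epo:double_decidual_sac_sign skos:prefLabel "double decidual sac sign" .
epo:embryo_with_cardiac_activity epo:definition "Embryonic pole with visible heartbeat." .
epo:embryo_with_cardiac_activity epo:kind "sign" .
epo:embryo_with_cardiac_activity epo:requires_view epo:uterus_sagittal_view .
epo:embryo_with_cardiac_activity epo:suggests epo:intrauterine_pregnancy .
epo:embryo_with_cardiac_activity skos:prefLabel "embryo with cardiac activity" .
epo:empty_adnexa epo:definition "No adnexal mass on either side." .
epo:empty_adnexa epo:kind "sign" .
epo:empty_adnexa epo:requires_view epo:left_adnexal_view .
epo:empty_adnexa epo:requires_view epo:right_adnexal_view .
epo:empty_adnexa epo:suggests epo:pregnancy_of_unknown_location .
epo:empty_adnexa skos:prefLabel "empty adnexa" .
epo:empty_uterine_cavity epo:definition "No gestational sac within the endometrial cavity." .
epo:empty_uterine_cavity epo:kind "sign" .
epo:empty_uterine_cavity epo:requires_view epo:uterus_sagittal_view .
epo:empty_uterine_cavity epo:requires_view epo:uterus_transverse_view .
epo:empty_uterine_cavity epo:suggests epo:pregnancy_of_unknown_location .
epo:empty_uterine_cavity epo:suggests epo:tubal_ectopic_pregnancy .
epo:empty_uterine_cavity skos:prefLabel "empty uterine cavity" .
epo:endometrium epo:kind "anatomical_structure" .
epo:endometrium epo:located_in epo:uterus .
epo:endometrium skos:prefLabel "endometrium" .
epo:endometrium_magnified_view epo:kind "echographic_view" .
epo:endometrium_magnified_view skos:prefLabel "magnified view of the endometrium" .
epo:fallopian_tube epo:kind "anatomical_structure" .
epo:fallopian_tube skos:prefLabel "fallopian tube" .
epo:free_fluid_pouch_of_douglas epo:definition "Anechoic or echogenic fluid behind the uterus." .
epo:free_fluid_pouch_of_douglas epo:kind "sign" .
epo:free_fluid_pouch_of_douglas epo:requires_view epo:pouch_of_douglas_view .
epo:free_fluid_pouch_of_douglas epo:suggests epo:tubal_ectopic_pregnancy .
epo:free_fluid_pouch_of_douglas skos:prefLabel "free fluid in the pouch of Douglas" .
epo:intrauterine_gestational_sac epo:definition "Gestational sac within the endometrial cavity." .
epo:intrauterine_gestational_sac epo:kind "sign" .
epo:intrauterine_gestational_sac epo:requires_view epo:uterus_sagittal_view .
epo:intrauterine_gestational_sac epo:requires_view epo:uterus_transverse_view .
epo:intrauterine_gestational_sac epo:suggests epo:intrauterine_pregnancy .
epo:intrauterine_gestational_sac skos:prefLabel "intrauterine gestational sac" .
epo:intrauterine_pregnancy epo:definition "Pregnancy implanted within the endometrial cavity." .
epo:intrauterine_pregnancy epo:has_sign epo:double_decidual_sac_sign .
epo:intrauterine_pregnancy epo:has_sign epo:embryo_with_cardiac_activity .
epo:intrauterine_pregnancy epo:has_sign epo:intrauterine_gestational_sac .
epo:intrauterine_pregnancy epo:has_sign epo:yolk_sac_visible .
epo:intrauterine_pregnancy epo:kind "disorder" .
epo:intrauterine_pregnancy skos:prefLabel "intrauterine pregnancy" .
epo:left_adnexal_view epo:kind "echographic_view" .
epo:left_adnexal_view skos:prefLabel "left adnexal view" .
epo:m_mode epo:kind "ultrasound_mode" .
epo:m_mode skos:prefLabel "M mode" .
epo:ovary epo:kind "anatomical_structure" .
epo:ovary skos:prefLabel "ovary" .
epo:pouch_of_douglas_view epo:kind "echographic_view" .
epo:pouch_of_douglas_view skos:prefLabel "view of the pouch of Douglas" .
epo:pregnancy_of_unknown_location epo:definition "Positive pregnancy test with no pregnancy visualized." .
epo:pregnancy_of_unknown_location epo:has_sign epo:empty_adnexa .
epo:pregnancy_of_unknown_location epo:has_sign epo:empty_uterine_cavity .
epo:pregnancy_of_unknown_location epo:kind "disorder" .
epo:pregnancy_of_unknown_location skos:prefLabel "pregnancy of unknown location" .
epo:pseudogestational_sac epo:definition "Intracavitary fluid mimicking a gestational sac." .
epo:pseudogestational_sac epo:kind "sign" .
epo:pseudogestational_sac epo:requires_view epo:uterus_sagittal_view .
epo:pseudogestational_sac epo:suggests epo:tubal_ectopic_pregnancy .
epo:pseudogestational_sac skos:prefLabel "pseudogestational sac" .
epo:right_adnexal_view epo:kind "echographic_view" .
epo:right_adnexal_view skos:prefLabel "right adnexal view" .
epo:transabdominal_route epo:kind "ultrasound_route" .
epo:transabdominal_route skos:prefLabel "transabdominal route" .
epo:transvaginal_route epo:kind "ultrasound_route" .
epo:transvaginal_route skos:prefLabel "transvaginal route" .
epo:tubal_ectopic_pregnancy epo:definition "Pregnancy implanted in the fallopian tube." .
epo:tubal_ectopic_pregnancy epo:has_sign epo:adnexal_blob_sign .
epo:tubal_ectopic_pregnancy epo:has_sign epo:adnexal_mass_separate_from_ovary .
epo:tubal_ectopic_pregnancy epo:has_sign epo:bagel_sign .
epo:tubal_ectopic_pregnancy epo:has_sign epo:empty_uterine_cavity .
epo:tubal_ectopic_pregnancy epo:has_sign epo:free_fluid_pouch_of_douglas .
epo:tubal_ectopic_pregnancy epo:has_sign epo:pseudogestational_sac .
epo:tubal_ectopic_pregnancy epo:kind "disorder" .
epo:tubal_ectopic_pregnancy skos:prefLabel "tubal ectopic pregnancy" .
epo:uterus epo:kind "anatomical_structure" .
epo:uterus skos:prefLabel "uterus" .
epo:uterus_sagittal_view epo:kind "echographic_view" .
epo:uterus_sagittal_view skos:prefLabel "sagittal view of the uterus" .
epo:uterus_transverse_view epo:kind "echographic_view" .
epo:uterus_transverse_view skos:prefLabel "transverse view of the uterus" .
epo:yolk_sac_visible epo:definition "Yolk sac within the gestational sac." .
epo:yolk_sac_visible epo:kind "sign" .
epo:yolk_sac_visible epo:requires_view epo:uterus_sagittal_view .
epo:yolk_sac_visible epo:suggests epo:intrauterine_pregnancy .
epo:yolk_sac_visible skos:prefLabel "yolk sac visible" .
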