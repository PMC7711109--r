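participant_id	gender_self	gender_std	pronouns	race_self	race_std	ethnicity_self	ethnicity_std	sexual_orientation_self	sexual_orientation_std	education	employment	income_bracket	has_insurance	languages
p01	Male	Male	He/Him/His	African American, White	Multi-racial	African American, Scottish	Not Hispanic or Latino	Heterosexual	Straight/Heterosexual	Master's degree	Working for pay	$50,000-$99,999	yes	English only
p02	Male	Male	He/Him/His	African American	Black or African American	No response	Not Hispanic or Latino	Heterosexual	Straight/Heterosexual	Bachelor's degree	Working for pay	$20,000-$49,999	yes	English only
p03	Female	Female	She/Her/Hers	Purepecha, Indigenous	American Indian or Alaska Native	Purepecha	Hispanic or Latino	Lesbian	Lesbian/Gay/Homosexual	Master's degree	Working for pay	$0-$19,999	no	English and other language(s)
p04	Cisgender male	Male	He/Him/His	Asian American	Asian	Korean American	Not Hispanic or Latino	Heterosexual	Straight/Heterosexual	Doctoral degree	Working for pay	Over $100,000	yes	English and other language(s)
p05	Male	Male	He/Him/His	Pilipino-AM	Asian	Pilipino-American	Not Hispanic or Latino	No response	Lesbian/Gay/Homosexual	Master's degree	Student	$0-$19,999	no	English and other language(s)
p06	Woman	Female	She/Her/Hers	South Asian Indian	Asian	Gujarati, Indian, South Asian American	Not Hispanic or Latino	Heterosexual	Straight/Heterosexual	Master's degree	Working for pay	$50,000-$99,999	yes	English and other language(s)
p07	Male	Male	He/Him/His	No response	Asian	Buddhist	Not Hispanic or Latino	Infrequent	Straight/Heterosexual	Some graduate work	Working for pay	$20,000-$49,999	yes	English only
p08	Cisgender male	Male	He/Him/His	White	White	Jewish, English	Not Hispanic or Latino	No response	Straight/Heterosexual	Master's degree	Working for pay	Over $100,000	yes	English only
p09	Female	Female	She/Her/Hers	White	White	Midwestern	Not Hispanic or Latino	Bisexual	Bisexual/Pansexual	Bachelor's degree	Working for pay	$50,000-$99,999	yes	English only
p10	Male	Male	He/Him/His	White	White	Iranian	Hispanic or Latino	Queer	Do Not Wish to Specify	Doctoral degree	Working for pay	Over $100,000	yes	English and other language(s)
p11	Male	Male	He/Him/His	Black	Multi-racial	No response	Not Hispanic or Latino	No response	Lesbian/Gay/Homosexual	Master's degree	Working for pay	$50,000-$99,999	yes	English only
p12	Cisgender female	Female	She/Her/Hers	Black	Multi-racial	No response	Not Hispanic or Latino	Queer	Lesbian/Gay/Homosexual	Master's degree	Unemployed and looking for work	$0-$19,999	no	English only
p13	Cis male	Male	Other: He/Him/They	Chicano, Native, White	Multi-racial	Chicano/Native American and White	Hispanic or Latino	No response	Straight/Heterosexual	Some graduate work	Working for pay	$20,000-$49,999	yes	English and other language(s)
p14	Woman	Female	She/Her/Hers	Latinx	Multi-racial	Latinx, Chicanx, Halfsican, Queer	Hispanic or Latino	Queer	Bisexual/Pansexual	Bachelor's degree	Student	$20,000-$49,999	yes	English only
p15	Queer	Another identity	They/Them/Theirs	Latinx/Mixed	Multi-racial	No response	Not Hispanic or Latino	Queer	Asexual	Master's degree	No response	$50,000-$99,999	yes	No response
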