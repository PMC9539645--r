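post_id,author_id,timestamp,text
n01,sunny22,2018-07-03,"Welcome to the forum, we are so glad you found us. You are not alone here."
n02,riverbed,2018-07-19,"I slept badly again last night. The racing thoughts keep coming back and I feel exhausted."
n03,riverbed,2018-08-02,"Talking about my sleep problems here helped me learn what works for me. Thanks everyone. - riverbed"
n04,quietfox,2018-08-21,"My psychologist taught me a breathing exercise. Practising it every morning is slowly building my confidence."
n05,riverbed,2018-09-10,"Short one today."
n06,lantern7,2018-09-28,"Reading everyone's stories makes me feel like I belong somewhere. This community means a lot."
n07,quietfox,2018-10-05,"I went back to work this week. Small steps, but I managed the anxiety better than last time."
n08,sunny22,2018-10-22,"Happy birthday lantern7! Hope you are doing something kind for yourself today."
n09,mosswalk,2018-11-08,"Does anyone have tips for telling friends about a diagnosis? I am worried about being judged."
n10,lantern7,2018-11-25,"mosswalk I told my closest friend first and her support gave me courage to tell the others."
n11,riverbed,2018-12-12,"The holidays are hard when family is far away. Grateful this forum stays open over Christmas."
n12,quietfox,2018-12-30,"New year, new goals. I am learning to notice my warning signs earlier and ask for help sooner."
n13,mosswalk,2019-01-14,"Thank you all. Knowing that others have walked this road makes the dark days easier."
n14,sunny22,2019-01-29,"Sending love to everyone struggling tonight. You matter and tomorrow can be different."
n15,lantern7,2019-02-11,"I started volunteering at the local garden. Meeting people slowly, at my own pace, feels safe."
n16,riverbed,2019-02-26,"ok"
n17,quietfox,2019-03-08,"A setback this week, but I used the skills from my plan and it passed without a crisis."
n18,mosswalk,2019-03-19,"The sleep diary idea from this thread really worked. Five nights of proper rest now."
n19,lantern7,2019-03-27,"Celebrating one year since I joined. This place taught me that asking for help is strength."
n20,sunny22,2019-03-31,"Checking in on everyone who posted this month. How are you travelling now?"
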